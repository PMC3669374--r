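>synthetic-histone-like-143-seed1
RGVNAHDQEKAAQGSLPMGSDAEARGKGIRLVLATQTKPGTESVLSKLPQLIGRKKRLQG
NRLRERLSKHRIGRLHIGSYGPGRSAPKRARKEHSTLGTEEGRMEAALNVFPGGAKPKGE
MLLASLLAAVVKKEDVVLFLQEA
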