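#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in alphabetical order. All sequences and
#' contact matrices in the package are indexed against this ordering.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a residue sequence
#'
#' A coarse-grained protein is represented by its ordered one-letter residue
#' codes; each residue becomes one node of the lattice chain.
#'
#' @param residues Character vector of one-letter codes, or a single string.
#' @param name Free-text label.
#' @return Object of class `residue_sequence`: character vector of codes with
#'   a `name` attribute.
#' @export
residue_sequence <- function(residues, name = "") {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  residues <- toupper(as.character(residues))
  if (length(residues) < 2L)
    stop("a residue sequence needs at least 2 residues")
  bad <- setdiff(unique(residues), aa_alphabet())
  if (length(bad) > 0L)
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  structure(residues, name = as.character(name)[1L], class = "residue_sequence")
}

#' @export
print.residue_sequence <- function(x, ...) {
  cat("residue_sequence '", attr(x, "name"), "': ", length(x), " residues\n",
      paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

# integer codes 0..19 into aa_alphabet(), as used by the C++ kernel
sequence_codes <- function(sequence) {
  match(unclass(sequence), aa_alphabet()) - 1L
}

#' Read a protein sequence from a FASTA file
#'
#' Reads the first record of a FASTA file; any letters outside the canonical
#' 20-letter alphabet are rejected with an error.
#'
#' @param path Path to a FASTA file.
#' @return A [residue_sequence()].
#' @export
read_fasta_sequence <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  residue_sequence(toupper(as.character(recs[[1L]])),
                   name = attr(recs[[1L]], "name"))
}

#' Write a residue sequence as FASTA
#'
#' @param sequence A [residue_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequence <- function(sequence, path) {
  nm <- attr(sequence, "name")
  if (is.null(nm) || !nzchar(nm)) nm <- "sequence"
  seqinr::write.fasta(list(unclass(sequence)), names = nm, file.out = path)
  invisible(path)
}
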