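,A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y
A,-1.2,-1.43333333333333,0.566666666666667,0.566666666666667,-1.53333333333333,-0.466666666666667,0.466666666666667,-2.1,0.7,-1.86666666666667,-1.23333333333333,0.566666666666667,-0.0666666666666667,0.566666666666667,0.9,-0.333333333333333,-0.366666666666667,-2,-0.3,-0.166666666666667
C,-1.43333333333333,-1.66666666666667,0.333333333333333,0.333333333333333,-1.76666666666667,-0.7,0.233333333333333,-2.33333333333333,0.466666666666667,-2.1,-1.46666666666667,0.333333333333333,-0.3,0.333333333333333,0.666666666666667,-0.566666666666667,-0.6,-2.23333333333333,-0.533333333333333,-0.4
D,0.566666666666667,0.333333333333333,2.33333333333333,2.33333333333333,0.233333333333333,1.3,2.23333333333333,-0.333333333333333,2.46666666666667,-0.0999999999999999,0.533333333333333,2.33333333333333,1.7,2.33333333333333,2.66666666666667,1.43333333333333,1.4,-0.233333333333333,1.46666666666667,1.6
E,0.566666666666667,0.333333333333333,2.33333333333333,2.33333333333333,0.233333333333333,1.3,2.23333333333333,-0.333333333333333,2.46666666666667,-0.0999999999999999,0.533333333333333,2.33333333333333,1.7,2.33333333333333,2.66666666666667,1.43333333333333,1.4,-0.233333333333333,1.46666666666667,1.6
F,-1.53333333333333,-1.76666666666667,0.233333333333333,0.233333333333333,-1.86666666666667,-0.8,0.133333333333333,-2.43333333333333,0.366666666666667,-2.2,-1.56666666666667,0.233333333333333,-0.4,0.233333333333333,0.566666666666667,-0.666666666666667,-0.7,-2.33333333333333,-0.633333333333333,-0.5
G,-0.466666666666667,-0.7,1.3,1.3,-0.8,0.266666666666667,1.2,-1.36666666666667,1.43333333333333,-1.13333333333333,-0.5,1.3,0.666666666666667,1.3,1.63333333333333,0.4,0.366666666666667,-1.26666666666667,0.433333333333333,0.566666666666667
H,0.466666666666667,0.233333333333333,2.23333333333333,2.23333333333333,0.133333333333333,1.2,2.13333333333333,-0.433333333333333,2.36666666666667,-0.2,0.433333333333333,2.23333333333333,1.6,2.23333333333333,2.56666666666667,1.33333333333333,1.3,-0.333333333333333,1.36666666666667,1.5
I,-2.1,-2.33333333333333,-0.333333333333333,-0.333333333333333,-2.43333333333333,-1.36666666666667,-0.433333333333333,-3,-0.2,-2.76666666666667,-2.13333333333333,-0.333333333333333,-0.966666666666667,-0.333333333333333,0,-1.23333333333333,-1.26666666666667,-2.9,-1.2,-1.06666666666667
K,0.7,0.466666666666667,2.46666666666667,2.46666666666667,0.366666666666667,1.43333333333333,2.36666666666667,-0.2,2.6,0.0333333333333334,0.666666666666667,2.46666666666667,1.83333333333333,2.46666666666667,2.8,1.56666666666667,1.53333333333333,-0.1,1.6,1.73333333333333
L,-1.86666666666667,-2.1,-0.0999999999999999,-0.0999999999999999,-2.2,-1.13333333333333,-0.2,-2.76666666666667,0.0333333333333334,-2.53333333333333,-1.9,-0.0999999999999999,-0.733333333333333,-0.0999999999999999,0.233333333333333,-1,-1.03333333333333,-2.66666666666667,-0.966666666666667,-0.833333333333333
M,-1.23333333333333,-1.46666666666667,0.533333333333333,0.533333333333333,-1.56666666666667,-0.5,0.433333333333333,-2.13333333333333,0.666666666666667,-1.9,-1.26666666666667,0.533333333333333,-0.0999999999999999,0.533333333333333,0.866666666666667,-0.366666666666667,-0.4,-2.03333333333333,-0.333333333333333,-0.2
N,0.566666666666667,0.333333333333333,2.33333333333333,2.33333333333333,0.233333333333333,1.3,2.23333333333333,-0.333333333333333,2.46666666666667,-0.0999999999999999,0.533333333333333,2.33333333333333,1.7,2.33333333333333,2.66666666666667,1.43333333333333,1.4,-0.233333333333333,1.46666666666667,1.6
P,-0.0666666666666667,-0.3,1.7,1.7,-0.4,0.666666666666667,1.6,-0.966666666666667,1.83333333333333,-0.733333333333333,-0.0999999999999999,1.7,1.06666666666667,1.7,2.03333333333333,0.8,0.766666666666667,-0.866666666666667,0.833333333333333,0.966666666666667
Q,0.566666666666667,0.333333333333333,2.33333333333333,2.33333333333333,0.233333333333333,1.3,2.23333333333333,-0.333333333333333,2.46666666666667,-0.0999999999999999,0.533333333333333,2.33333333333333,1.7,2.33333333333333,2.66666666666667,1.43333333333333,1.4,-0.233333333333333,1.46666666666667,1.6
R,0.9,0.666666666666667,2.66666666666667,2.66666666666667,0.566666666666667,1.63333333333333,2.56666666666667,0,2.8,0.233333333333333,0.866666666666667,2.66666666666667,2.03333333333333,2.66666666666667,3,1.76666666666667,1.73333333333333,0.0999999999999999,1.8,1.93333333333333
S,-0.333333333333333,-0.566666666666667,1.43333333333333,1.43333333333333,-0.666666666666667,0.4,1.33333333333333,-1.23333333333333,1.56666666666667,-1,-0.366666666666667,1.43333333333333,0.8,1.43333333333333,1.76666666666667,0.533333333333333,0.5,-1.13333333333333,0.566666666666667,0.7
T,-0.366666666666667,-0.6,1.4,1.4,-0.7,0.366666666666667,1.3,-1.26666666666667,1.53333333333333,-1.03333333333333,-0.4,1.4,0.766666666666667,1.4,1.73333333333333,0.5,0.466666666666667,-1.16666666666667,0.533333333333333,0.666666666666667
V,-2,-2.23333333333333,-0.233333333333333,-0.233333333333333,-2.33333333333333,-1.26666666666667,-0.333333333333333,-2.9,-0.1,-2.66666666666667,-2.03333333333333,-0.233333333333333,-0.866666666666667,-0.233333333333333,0.0999999999999999,-1.13333333333333,-1.16666666666667,-2.8,-1.1,-0.966666666666667
W,-0.3,-0.533333333333333,1.46666666666667,1.46666666666667,-0.633333333333333,0.433333333333333,1.36666666666667,-1.2,1.6,-0.966666666666667,-0.333333333333333,1.46666666666667,0.833333333333333,1.46666666666667,1.8,0.566666666666667,0.533333333333333,-1.1,0.6,0.733333333333333
Y,-0.166666666666667,-0.4,1.6,1.6,-0.5,0.566666666666667,1.5,-1.06666666666667,1.73333333333333,-0.833333333333333,-0.2,1.6,0.966666666666667,1.6,1.93333333333333,0.7,0.666666666666667,-0.966666666666667,0.733333333333333,0.866666666666667
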