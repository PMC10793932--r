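id,strength_mixing,centrality_mixing,strength_nesting,centrality_nesting,strength_shifting,centrality_shifting
AMA,0.95,0.39,1.77,0.43,1.52,0.51
ISA,0.50,0.20,0.92,0.24,0.55,0.25
ITE,0.53,0.21,0.56,0.16,0.38,0.16
KAL,0.57,0.24,1.05,0.28,0.79,0.32
KIG,0.91,0.37,1.00,0.27,0.62,0.26
LUB,0.32,0.13,0.82,0.19,0.40,0.15
LUL,0.63,0.25,0.92,0.29,0.49,0.16
MAP,0.77,0.34,0.95,0.31,0.75,0.32
MUY,0.96,0.38,0.94,0.24,0.79,0.30
NDJ,0.63,0.27,0.87,0.23,0.74,0.29
PIN,0.57,0.20,1.42,0.35,0.73,0.22
SER,0.44,0.16,0.80,0.23,0.47,0.14
SHA,0.57,0.22,0.82,0.19,0.71,0.23
TUM,0.54,0.21,0.71,0.19,0.40,0.14
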