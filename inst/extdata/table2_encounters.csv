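residue,wt_binding_time,wt_primary,wt_secondary,e60d_binding_time,e60d_primary,e60d_secondary
E4,4681,5,0,3282,4,0
E5,1,1,0,0,0,0
E11,3769,6,1,1331,1,1
Y13,0,0,0,1,0,1
A14,0,NA,NA,0,NA,NA
A15,0,0,0,1080,5,1
K16,2966,4,2,3296,5,2
E17,139336,51,10,269478,57,8
G18,1434,5,1,2878,4,0
D19,15339,10,7,1520,8,2
A21,4491,4,2,45288,6,3
Q22,67512,52,16,176169,37,18
L23,55,19,1,0,0,0
S24,1463,3,8,21335,15,11
E26,18961,6,5,18842,8,6
E27,24807,4,5,29762,6,5
K41,657,0,3,722,3,1
G42,841,9,2,1935,3,1
P43,89505,16,11,31363,8,2
S44,3254,4,10,1469,2,2
T45,1874,0,2,1,0,1
D47,62462,37,11,40492,25,4
E48,176802,55,7,92731,10,7
E51,159179,62,14,130802,42,8
E52,12894,15,3,3911,9,1
L53,0,0,0,2,0,1
D54,96269,17,22,94526,19,4
K55,1427,7,3,8392,16,2
A56,36670,28,6,85218,17,11
G57,73675,28,11,7737,11,2
D58,191748,58,19,385846,88,12
F59,20194,9,10,486,2,7
E60,269285,71,35,527753,165,27
S62,1033,14,16,3118,175,14
E64,31634,26,11,17635,28,2
E65,157857,26,12,21236,24,7
Q67,0,0,0,1,0,1
K72,0,0,0,56253,15,2
I73,22122,6,3,7630,15,2
S74,2531,16,2,11640,33,6
Q75,80,1,0,1238,2,1
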