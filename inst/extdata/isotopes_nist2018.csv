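element,isotope,mass_da,abundance
H,1,1.00782503207,0.999885
H,2,2.01410177785,0.000115
C,12,12.0000000,0.9893
C,13,13.00335483507,0.0107
N,14,14.0030740048,0.99636
N,15,15.0001088989,0.00364
O,16,15.99491461956,0.99757
O,17,16.99913170,0.00038
O,18,17.9991610,0.00205
P,31,30.97376163,1.0
S,32,31.97207100,0.9499
S,33,32.97145876,0.0075
S,34,33.96786690,0.0425
S,36,35.96708076,0.0001
Cl,35,34.96885268,0.7576
Cl,37,36.96590259,0.2424
Br,79,78.9183371,0.5069
Br,81,80.9162906,0.4931
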