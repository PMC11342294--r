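element,nucleon_number,mass_da,abundance
C,12,12.0,0.9893
C,13,13.0033548378,0.0107
H,1,1.0078250319,0.999885
H,2,2.0141017780,0.000115
N,14,14.0030740052,0.99636
N,15,15.0001088984,0.00364
O,16,15.9949146221,0.99757
O,17,16.9991315,0.00038
O,18,17.9991604,0.00205
P,31,30.97376151,1.0
S,32,31.97207100,0.9493
S,33,32.97145876,0.0076
S,34,33.96786690,0.0429
S,36,35.96708076,0.0002
F,19,18.99840320,1.0
Na,23,22.98976928,1.0
K,39,38.9637069,0.932581
K,40,39.9639992,0.000117
K,41,40.9618254,0.067302
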