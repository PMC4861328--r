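cum_fraction_upper,mpce_upper
0.05,827
0.10,983
0.20,1239
0.30,1490
0.40,1757
0.50,2019
0.60,2349
0.70,2771
0.80,3390
0.90,4610
0.95,6383
1.00,
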