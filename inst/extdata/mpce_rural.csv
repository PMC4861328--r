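cum_fraction_upper,mpce_upper
0.05,616
0.10,710
0.20,845
0.30,963
0.40,1075
0.50,1198
0.60,1341
0.70,1522
0.80,1793
0.90,2296
0.95,2886
1.00,
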