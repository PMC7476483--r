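# synthetic 1H line spectrum of ethanol (surrogate-predicted)
# one chemical shift (ppm) per proton
3.2921
3.2921
2.9766
0.9149
0.9149
0.9149
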