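class,low,medium_low,medium,medium_high,high
low,4989.00,823.19,144.50,23.44,5.63
medium_low,652.81,1711.44,902.75,167.56,37.50
medium,139.75,991.88,2075.94,1144.25,320.88
medium_high,43.25,212.94,1121.31,2066.25,1464.88
high,13.38,36.25,300.94,1264.13,4696.56
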