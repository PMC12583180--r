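class,low,medium_low,medium,medium_high,high
low,5424.69,1380.38,562.25,122.94,21.63
medium_low,458.38,1307.31,1345.88,510.94,100.06
medium,81.13,552.50,1329.88,1165.50,441.00
medium_high,15.94,175.00,1041.56,1699.00,1289.63
high,5.63,56.88,393.13,1410.25,4458.94
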