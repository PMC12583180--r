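class,low,medium_low,medium,medium_high,high
low,5257.19,1661.19,490.63,77.06,25.81
medium_low,412.69,1431.44,1360.63,427.13,90.69
medium,103.44,495.00,1416.75,1164.56,390.25
medium_high,37.94,130.19,940.31,1744.06,1368.63
high,26.94,57.88,337.13,1252.81,4650.06
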