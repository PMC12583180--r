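class,area_km2,percentage
low,3938.13,15.53
medium_low,3876.75,15.29
medium,5836.00,23.02
medium_high,6685.63,26.37
high,5013.88,19.78
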