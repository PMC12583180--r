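cv_class,percentage
stabilisation,17.09
slight_fluctuation,47.37
moderate_fluctuation,27.09
high_fluctuation,6.68
wild_fluctuation,1.76
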