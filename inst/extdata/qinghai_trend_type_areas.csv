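change_type,area_km2,percentage
significant_degradation,1369.94,5.40
insignificant_degradation,5573.06,21.98
stabilization,4640.31,18.30
insignificant_improvement,9197.62,36.28
significant_improvement,4569.31,18.02
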