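name: desoximetasone
molecular_weight: 376.46
log_p: 2.35
water_solubility: 0.0421
blood_plasma_ratio: 0.76
fu_plasma: 0.145
clearance_iv: 16.95
density: 1.3
compound_type: neutral
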