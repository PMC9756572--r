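dose_volume: 5.0
area: 0.5
receptor_volume: 12.0
duration: 24.0
sampling_times:
- 0.0
- 2.0
- 4.0
- 6.0
- 8.0
- 12.0
- 24.0
n_discarded_tape_strips: 3
temperature: 32.0
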