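- scenario: 1
  events:
  - start_h: 0.0
    duration_h: 12.0
    n_sprays: 5.0
    area_cm2: 50.0
  - start_h: 12.0
    duration_h: 12.0
    n_sprays: 5.0
    area_cm2: 50.0
- scenario: 2
  events:
  - start_h: 0.0
    duration_h: 12.0
    n_sprays: 25.0
    area_cm2: 50.0
  - start_h: 12.0
    duration_h: 12.0
    n_sprays: 25.0
    area_cm2: 50.0
- scenario: 3
  events:
  - start_h: 0.0
    duration_h: 12.0
    n_sprays: 50.0
    area_cm2: 50.0
  - start_h: 12.0
    duration_h: 12.0
    n_sprays: 50.0
    area_cm2: 50.0
- scenario: 4
  events:
  - start_h: 0.0
    duration_h: 12.0
    n_sprays: 175.0
    area_cm2: 50.0
  - start_h: 12.0
    duration_h: 12.0
    n_sprays: 175.0
    area_cm2: 50.0
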