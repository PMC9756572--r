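components:
- name: desoximetasone
  w_w_percent: 0.249975
  density_g_ml: 1.3
  volatile: no
  api: yes
- name: glyceryl oleate
  w_w_percent: 0.89991
  density_g_ml: 1.0
  volatile: no
  api: no
- name: isopropyl alcohol
  w_w_percent: 23.3976602
  density_g_ml: 0.774
  volatile: yes
  api: no
- name: isopropyl myristate
  w_w_percent: 31.3768623
  density_g_ml: 0.85
  volatile: no
  api: no
- name: l-menthol
  w_w_percent: 0.049995
  density_g_ml: 0.89
  volatile: no
  api: no
- name: mineral oil
  w_w_percent: 44.0255974
  density_g_ml: 0.85
  volatile: no
  api: no
q3:
  viscosity_cP: 100.0
  solubility_mg_ml: 0.55
  max_evaporated_pct_vv: 25.1730951
  evaporation_rate_ml_h: 5.0
  molar_volume_cont_phase: 415.8
  evaporation_basis: per_dose
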