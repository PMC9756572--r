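n_sc_layers: 20
sc_layer_thickness: 0.75
viable_epidermis_thickness: 100.0
dermis_thickness: 500.0
K_sclip_vehicle: 2.0
P_cell: 0.02
D_sclip: 3.85e-07
f_sc_lipid: 0.1
K_corneocyte_water: 3.0
D_ve: 0.00083
D_dermis: 0.0037
K_ve_water: 0.6
K_dermis_water: 0.17
fu_dermis: 0.054
capillary_radius_scale: 1.0
fraction_capillaries_perfused: 1.0
baseline_dermis_blood_flow: 4.0
body_site: abdomen (scenario B)
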