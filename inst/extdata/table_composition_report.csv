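"component","density_g_ml","primary_w_w_pct","tertiary_w_w_pct","primary_v_v_pct","tertiary_v_v_pct"
"desoximetasone",1.3,0.24997500249975,0.326328155593265,0.160124717462657,0.213993506364928
"glyceryl oleate",1,0.8999100089991,1.17478136013575,0.749383677725234,1.00148960978786
"isopropyl alcohol",0.774,23.3976602339766,0,25.1730951173851,0
"isopropyl myristate",0.85,31.3768623137686,40.9607100900666,30.7394245843371,41.0807110524747
"l-menthol",0.89,0.04999500049995,0.0652656311186529,0.0467780073486413,0.0625149569155969
"mineral oil",0.85,44.025597440256,57.4729147630857,43.1311938957413,57.641290874457
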