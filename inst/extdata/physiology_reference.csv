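tissue,vol_frac_bw,flow_frac_co
lung,0.011,NA
adipose,0.19,0.05
muscle,0.40,0.17
liver,0.026,0.215
spleen,0.0026,0.03
heart,0.005,0.04
brain,0.02,0.12
kidney,0.0044,0.19
skin,0.037,0.058
reproductive,0.0005,0.002
red_marrow,0.014,0.03
yellow_marrow,0.03,0.005
rest_of_body,0.15,NA
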