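tissue,kp
lung,7.83
adipose,0.55
muscle,3.27
liver,9.01
spleen,6.70
heart,3.01
brain,3.01
kidney,3.01
skin,3.21
reproductive,9.75
red_marrow,2.27
yellow_marrow,2.27
rest_of_body,6.70
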