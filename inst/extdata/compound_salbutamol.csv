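parameter,value,units
molecular_weight,239.32,g/mol
logP,0.76,
pKa_basic,9.34,
pKa_acidic,10.52,
solubility,14.47,mg/mL at pH 9.93
diffusion_coeff,0.804e-5,cm^2/s
blood_plasma_ratio,1.108,
effective_permeability,1.21e-4,cm/s
fraction_unbound,0.7965,fraction
hepatic_clearance,38.06,L/h plasma
renal_clearance,16.32,L/h plasma
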