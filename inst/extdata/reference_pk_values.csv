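metric,observed,predicted
fa_percent,85.2,87.7
f_percent,52.4,47.4
cmax_ug_ml,0.00725,0.00919
tmax_h,2.35,1.28
auc_inf_ug_h_ml,0.0318,0.0553
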