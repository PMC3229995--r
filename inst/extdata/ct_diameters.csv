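object,state,mean_mm,sd_mm,repeat_sd_mm
cup,unworn,54.37,5.14,0.034
cup,worn,54.77,5.12,0.030
head,unworn,28.04,0.06,0.041
head,worn,27.86,0.05,0.045
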