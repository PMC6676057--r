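variable,animal1,animal2,animal3,animal4,animal5,animal6,animal7,animal8,printed_mean
weight_kg,46.5,45,39,53,37,37,47,44.5,43.6
hr_bpm,75,70,100,87,60,87,70,102,81
sbp_mmhg,113,101,105,80,130,95,105,95,103
dbp_mmhg,87,62,71,60,90,85,75,65,74
qt_lmin,2.9,6.2,5,4.4,3.9,3.2,6.7,3.7,4.5
qist_lmin,3.9,6,4.1,4.9,8.1,5.6,7.2,9.2,6.1
pap_mmhg,20,16,18,15,17,18,16,21,18
hb_gdl,7.8,8.2,8.9,8.3,10.2,8.3,8.8,9.6,8.8
fio2,0.6,0.28,0.4,0.4,0.35,0.4,0.4,0.4,0.4
sao2_pct,99,99,100,99,95,97,100,97,98
ph,7.37,7.48,7.49,7.38,7.31,7.33,7.33,7.24,7.36
pao2_mmhg,304,115,163,160,186,196,164,175,182
paco2_mmhg,59,45,44,46,60,56,58,60,53.5
pfr_mmhg,507,411,408,400,531,490,410,438,449
paw_peak_cmh2o,15,14,16,18,16,16,15,13,15
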