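genotype,condition,timepoint,mfr_pct,sem_pct
WT,bicuculline,baseline,100,0
WT,bicuculline,2h,147.58,10.05
WT,bicuculline,48h,101.38,0.7
Lgdel,bicuculline,baseline,100,0
Lgdel,bicuculline,2h,79.88,4.48
Lgdel,bicuculline,48h,64.11,3.13
Dgcr8,bicuculline,baseline,100,0
Dgcr8,bicuculline,2h,61.01,1.56
Dgcr8,bicuculline,48h,89.12,2.15
WT,bumetanide+bicuculline,baseline,100,0
WT,bumetanide+bicuculline,2h,140.06,8.74
WT,bumetanide+bicuculline,48h,96.7,6.35
Lgdel,bumetanide+bicuculline,baseline,100,0
Lgdel,bumetanide+bicuculline,2h,133.55,6.19
Lgdel,bumetanide+bicuculline,48h,94.95,11.09
WT,untreated,baseline,100,0
WT,untreated,16div,89.98,12.86
WT,untreated,18div,88.21,14.38
Lgdel,untreated,baseline,100,0
Lgdel,untreated,16div,147.51,5.58
Lgdel,untreated,18div,139.53,1.03
Lgdel,untreated,26div,83.76,8.05
WT,bumetanide,baseline,100,0
WT,bumetanide,16div,88.17,2.46
WT,bumetanide,18div,87.8,4.14
Lgdel,bumetanide,baseline,100,0
Lgdel,bumetanide,16div,74.53,7.69
Lgdel,bumetanide,18div,83.76,8.05
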