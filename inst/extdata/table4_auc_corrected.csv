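study,contrast,biomarker,auc,ci_low,ci_high
Alder Hey ED,SBI_vs_nonSBI,NGAL,0.65,0.62,0.69
Alder Hey ED,DB_vs_DV,NGAL,0.73,0.65,0.81
Alder Hey ED,SBI_vs_nonSBI,resistin,0.65,0.61,0.69
Alder Hey ED,DB_vs_DV,resistin,0.70,0.61,0.78
Alder Hey ED,SBI_vs_nonSBI,PCT,0.65,0.62,0.69
Alder Hey ED,DB_vs_DV,PCT,0.79,0.69,0.89
Alder Hey ED,SBI_vs_nonSBI,combined,0.71,0.67,0.74
Alder Hey ED,DB_vs_DV,combined,0.81,0.73,0.88
Alder Hey PICU,SBI_vs_nonSBI,NGAL,0.62,0.51,0.73
Alder Hey PICU,DB_vs_DV,NGAL,0.75,0.63,0.88
Alder Hey PICU,SBI_vs_nonSBI,resistin,0.58,0.47,0.69
Alder Hey PICU,DB_vs_DV,resistin,0.65,0.50,0.79
Alder Hey PICU,SBI_vs_nonSBI,PCT,0.67,0.59,0.75
Alder Hey PICU,DB_vs_DV,PCT,0.77,0.69,0.84
Alder Hey PICU,SBI_vs_nonSBI,combined,0.70,0.60,0.80
Alder Hey PICU,DB_vs_DV,combined,0.87,0.77,0.96
Erasmus ED,SBI_vs_nonSBI,PCT,0.75,0.69,0.80
Erasmus ED,DB_vs_DV,PCT,0.76,0.65,0.86
Maasstad ED,SBI_vs_nonSBI,PCT,0.74,0.67,0.81
Maasstad ED,DB_vs_DV,PCT,0.76,0.64,0.88
St. Mary's,SBI_vs_nonSBI,NGAL,0.80,0.74,0.86
St. Mary's,DB_vs_DV,NGAL,0.90,0.82,0.97
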