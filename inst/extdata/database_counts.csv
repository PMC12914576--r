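database,n_patients
ACRIN,3
CPTAC-GBM,33
EGD,774
IvyGAP,29
REMBRANDT,48
TCGA-GBM-LGG,166
UCSF-PDGM,500
UPENN-GBM,611
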