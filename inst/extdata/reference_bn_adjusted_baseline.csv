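sex,var_a,var_b,strength
male,iam,iaa,1
male,trp,kyn,1
male,kyna,xa,1
male,ser,hiaa,0.93
male,kyn,haa,0.90
male,pic,aa,0.88
female,kyna,iaa,1
female,kyn,hk,1
female,ipa,icho,0.98
female,trp,ser,0.95
female,iam,iaa,0.94
female,pic,htp,0.93
female,haa,trm,0.91
female,hk,haa,0.90
female,kyna,qa,0.88
female,trp,kyn,0.85
female,qa,xa,0.85
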