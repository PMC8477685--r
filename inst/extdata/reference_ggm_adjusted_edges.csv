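sex,timepoint,var_a,var_b,pcor
male,baseline,iam,iaa,0.57
male,baseline,trp,kyn,0.42
male,baseline,kyna,xa,0.40
male,baseline,kyn,haa,0.36
male,baseline,haa,trm,0.33
male,baseline,pic,aa,-0.31
male,followup,kyna,xa,0.45
male,followup,pic,htp,-0.36
male,followup,iam,iaa,0.31
male,followup,trp,kyn,0.31
female,baseline,kyn,hk,0.47
female,baseline,kyna,iaa,0.41
female,baseline,trp,ser,0.37
female,baseline,hk,haa,0.34
female,followup,kyna,iaa,0.45
female,followup,hk,haa,0.42
female,followup,kyn,hk,0.39
female,followup,ipa,icho,0.31
female,followup,xa,hiaa,0.30
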