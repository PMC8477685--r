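sex,change,var_a,var_b
male,absent,iam,iaa
male,absent,ser,hiaa
male,absent,kyn,haa
male,absent,pic,aa
male,new,pic,htp
male,new,kyna,ser
male,new,kyn,hk
female,absent,trp,ser
female,absent,pic,htp
female,absent,haa,trm
female,absent,qa,xa
female,new,pic,ser
female,new,kyna,hiaa
female,new,xa,ser
female,new,xa,hiaa
female,new,aa,htp
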