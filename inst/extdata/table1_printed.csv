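study_id,annuity,greenery_value,eur_base_value,unit_value
peck1999,12599,1323,1044,20.88
hunt2008,12599,1134,895,17.90
gao2007_tokyo,32998,8400,87,3.46
gao2007_kitakyushu,4010,1980,17,0.69
ichihara2010,4000,648,859,17.18
desrosiers2002,6135,239,189,3.78
tomalty2010_recreational,21662,4332,3174,63.47
tomalty2010_productive,21662,1516,1111,22.22
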