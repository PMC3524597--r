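study_id,unit_value,weight
peck1999,20.88,0.048
hunt2008,17.90,0.027
gao2007_tokyo,3.46,0.368
gao2007_kitakyushu,0.69,6.351
ichihara2010,17.18,0.014
desrosiers2002,3.78,0.281
tomalty2010_recreational,63.47,0.001
tomalty2010_productive,22.22,0.008
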