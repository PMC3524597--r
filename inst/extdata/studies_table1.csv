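study_id,study_label,data_year,location,currency,price_kind,price,price_ref,premium_lo,premium_hi,premium_base,greenery_area,uncertainty,rel_se
peck1999,Peck et al. (1999),1999,"Canada, Toronto",CAD,property-price,230000,,6,15,annuity,50,interval,
hunt2008,Hunt (2008),1999,"Canada, Toronto",CAD,property-price,,peck1999,3,15,annuity,50,interval,
gao2007_tokyo,Gao & Asami (2007),1999,"Japan, Tokyo",JPY,property-price,602400,,1.4,1.4,property-price,25,reported-se,0.476430
gao2007_kitakyushu,Gao & Asami (2007),2003,"Japan, Kitakyushu",JPY,property-price,73200,,2.7,2.7,property-price,25,reported-se,0.575055
ichihara2010,Ichihara & Cohen (2010),2000,"US, New York",USD,annual-rent,4000,,16.2,16.2,annuity,50,reported-se,0.491940
desrosiers2002,Des Rosiers et al. (2002),1999,"Canada, Quebec",CAD,property-price,112000,,3.9,3.9,annuity,50,reported-se,0.499068
tomalty2010_recreational,Tomalty & Komorowski (2010),2010,"Canada, Toronto",CAD,property-price,395460,,20,20,annuity,50,none,
tomalty2010_productive,Tomalty & Komorowski (2010),2010,"Canada, Toronto",CAD,property-price,395460,,7,7,annuity,50,none,
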