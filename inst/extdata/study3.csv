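"study_id","participant_id","formulation_id","age_years","taste_score","willing_binary","willing_choice","willing_score"
"study3","P01","FLX TMT1",,2,,"FLX TMT1",
"study3","P02","FLX TMT1",,2,,"FLX TMT1",
"study3","P03","FLX TMT1",,2,,"FLX TMT1",
"study3","P04","FLX TMT1",,2,,"FLX TMT1",
"study3","P05","FLX TMT1",,2,,"FLX TMT1",
"study3","P06","FLX TMT1",,3,,"FLX TMT1",
"study3","P07","FLX TMT1",,3,,"FLX TMT1",
"study3","P08","FLX TMT1",,3,,"FLX TMT1",
"study3","P09","FLX TMT1",,4,,"FLX TMT1",
"study3","P10","FLX TMT1",,4,,"FLX TMT1",
"study3","P11","FLX TMT1",,4,,"FLX TMT1",
"study3","P12","FLX TMT1",,4,,"FLX TMT2",
"study3","P13","FLX TMT1",,4,,"FLX TMT2",
"study3","P14","FLX TMT1",,4,,"FLX TMT2",
"study3","P15","FLX TMT1",,4,,"FLX TMT2",
"study3","P16","FLX TMT1",,4,,"FLX TMT2",
"study3","P17","FLX TMT1",,4,,"FLX TMT2",
"study3","P18","FLX TMT1",,4,,"FLX TMT2",
"study3","P19","FLX TMT1",,5,,"FLX TMT2",
"study3","P20","FLX TMT1",,5,,"FLX TMT2",
"study3","P21","FLX TMT1",,5,,"FLX LQD",
"study3","P01","FLX TMT2",,1,,"FLX TMT1",
"study3","P02","FLX TMT2",,1,,"FLX TMT1",
"study3","P03","FLX TMT2",,1,,"FLX TMT1",
"study3","P04","FLX TMT2",,2,,"FLX TMT1",
"study3","P05","FLX TMT2",,2,,"FLX TMT1",
"study3","P06","FLX TMT2",,2,,"FLX TMT1",
"study3","P07","FLX TMT2",,3,,"FLX TMT1",
"study3","P08","FLX TMT2",,3,,"FLX TMT1",
"study3","P09","FLX TMT2",,3,,"FLX TMT1",
"study3","P10","FLX TMT2",,3,,"FLX TMT1",
"study3","P11","FLX TMT2",,3,,"FLX TMT1",
"study3","P12","FLX TMT2",,4,,"FLX TMT2",
"study3","P13","FLX TMT2",,4,,"FLX TMT2",
"study3","P14","FLX TMT2",,4,,"FLX TMT2",
"study3","P15","FLX TMT2",,4,,"FLX TMT2",
"study3","P16","FLX TMT2",,4,,"FLX TMT2",
"study3","P17","FLX TMT2",,4,,"FLX TMT2",
"study3","P18","FLX TMT2",,4,,"FLX TMT2",
"study3","P19","FLX TMT2",,5,,"FLX TMT2",
"study3","P20","FLX TMT2",,5,,"FLX TMT2",
"study3","P21","FLX TMT2",,5,,"FLX LQD",
"study3","P01","FLX LQD",,1,,"FLX TMT1",
"study3","P02","FLX LQD",,1,,"FLX TMT1",
"study3","P03","FLX LQD",,1,,"FLX TMT1",
"study3","P04","FLX LQD",,1,,"FLX TMT1",
"study3","P05","FLX LQD",,1,,"FLX TMT1",
"study3","P06","FLX LQD",,1,,"FLX TMT1",
"study3","P07","FLX LQD",,1,,"FLX TMT1",
"study3","P08","FLX LQD",,1,,"FLX TMT1",
"study3","P09","FLX LQD",,2,,"FLX TMT1",
"study3","P10","FLX LQD",,2,,"FLX TMT1",
"study3","P11","FLX LQD",,2,,"FLX TMT1",
"study3","P12","FLX LQD",,2,,"FLX TMT2",
"study3","P13","FLX LQD",,2,,"FLX TMT2",
"study3","P14","FLX LQD",,2,,"FLX TMT2",
"study3","P15","FLX LQD",,2,,"FLX TMT2",
"study3","P16","FLX LQD",,3,,"FLX TMT2",
"study3","P17","FLX LQD",,3,,"FLX TMT2",
"study3","P18","FLX LQD",,3,,"FLX TMT2",
"study3","P19","FLX LQD",,4,,"FLX TMT2",
"study3","P20","FLX LQD",,4,,"FLX TMT2",
"study3","P21","FLX LQD",,5,,"FLX LQD",
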