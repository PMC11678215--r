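"study_id","participant_id","formulation_id","age_years","taste_score","willing_binary","willing_choice","willing_score"
"study4","P01","PSP TMT",,3,,"PSP TMT",4
"study4","P02","PSP TMT",,4,,"PSP TMT",4
"study4","P03","PSP TMT",,4,,"PSP TMT",4
"study4","P04","PSP TMT",,5,,"PSP TMT",7
"study4","P05","PSP TMT",,5,,"PSP TMT",7
"study4","P06","PSP TMT",,6,,"PSP TMT",7
"study4","P07","PSP TMT",,6,,"PSP TMT",7
"study4","P08","PSP TMT",,6,,"PSP TMT",7
"study4","P09","PSP TMT",,7,,"PSP TMT",7
"study4","P10","PSP TMT",,7,,"PSP TMT",7
"study4","P11","PSP TMT",,7,,"PSP TMT",7
"study4","P12","PSP TMT",,7,,"PSP TMT",7
"study4","P13","PSP TMT",,7,,"PSP TMT",8
"study4","P14","PSP TMT",,7,,"PSP TMT",8
"study4","P15","PSP TMT",,8,,"PSP LQD",8
"study4","P16","PSP TMT",,8,,"PSP LQD",8
"study4","P17","PSP TMT",,8,,"PSP LQD",8
"study4","P18","PSP TMT",,8,,"PSP LQD",8
"study4","P19","PSP TMT",,8,,"PSP LQD",8
"study4","P20","PSP TMT",,8,,"PSP LQD",8
"study4","P21","PSP TMT",,8,,"PSP LQD",8
"study4","P22","PSP TMT",,10,,"PSP LQD",9
"study4","P23","PSP TMT",,10,,"PSP LQD",9
"study4","P24","PSP TMT",,10,,"PSP LQD",9
"study4","P25","PSP TMT",,10,,"PSP LQD",9
"study4","P01","PSP LQD",,2,,"PSP TMT",4
"study4","P02","PSP LQD",,2,,"PSP TMT",4
"study4","P03","PSP LQD",,2,,"PSP TMT",4
"study4","P04","PSP LQD",,2,,"PSP TMT",4
"study4","P05","PSP LQD",,2,,"PSP TMT",4
"study4","P06","PSP LQD",,5,,"PSP TMT",4
"study4","P07","PSP LQD",,5,,"PSP TMT",5
"study4","P08","PSP LQD",,5,,"PSP TMT",5
"study4","P09","PSP LQD",,5,,"PSP TMT",5
"study4","P10","PSP LQD",,5,,"PSP TMT",6
"study4","P11","PSP LQD",,5,,"PSP TMT",6
"study4","P12","PSP LQD",,5,,"PSP TMT",6
"study4","P13","PSP LQD",,5,,"PSP TMT",6
"study4","P14","PSP LQD",,6,,"PSP TMT",6
"study4","P15","PSP LQD",,6,,"PSP LQD",7
"study4","P16","PSP LQD",,6,,"PSP LQD",7
"study4","P17","PSP LQD",,6,,"PSP LQD",8
"study4","P18","PSP LQD",,6,,"PSP LQD",8
"study4","P19","PSP LQD",,6,,"PSP LQD",8
"study4","P20","PSP LQD",,6,,"PSP LQD",9
"study4","P21","PSP LQD",,9,,"PSP LQD",9
"study4","P22","PSP LQD",,9,,"PSP LQD",9
"study4","P23","PSP LQD",,10,,"PSP LQD",9
"study4","P24","PSP LQD",,10,,"PSP LQD",9
"study4","P25","PSP LQD",,10,,"PSP LQD",9
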