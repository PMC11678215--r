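"study_id","participant_id","formulation_id","age_years","taste_score","willing_binary","willing_choice","willing_score"
"study2","TRM_TMT_001","TRM TMT",3,1,"no",,
"study2","TRM_TMT_002","TRM TMT",4,2,"no",,
"study2","TRM_TMT_003","TRM TMT",5,2,"no",,
"study2","TRM_TMT_004","TRM TMT",6,2,"no",,
"study2","TRM_TMT_005","TRM TMT",3,2,"no",,
"study2","TRM_TMT_006","TRM TMT",4,2,"no",,
"study2","TRM_TMT_007","TRM TMT",5,2,"no",,
"study2","TRM_TMT_008","TRM TMT",6,3,"no",,
"study2","TRM_TMT_009","TRM TMT",3,3,"no",,
"study2","TRM_TMT_010","TRM TMT",4,3,"no",,
"study2","TRM_TMT_011","TRM TMT",5,3,"no",,
"study2","TRM_TMT_012","TRM TMT",6,3,"no",,
"study2","TRM_TMT_013","TRM TMT",3,3,"no",,
"study2","TRM_TMT_014","TRM TMT",4,3,"no",,
"study2","TRM_TMT_015","TRM TMT",5,3,"no",,
"study2","TRM_TMT_016","TRM TMT",6,3,"yes",,
"study2","TRM_TMT_017","TRM TMT",3,3,"yes",,
"study2","TRM_TMT_018","TRM TMT",4,3,"yes",,
"study2","TRM_TMT_019","TRM TMT",5,3,"yes",,
"study2","TRM_TMT_020","TRM TMT",6,3,"yes",,
"study2","TRM_TMT_021","TRM TMT",3,3,"yes",,
"study2","TRM_TMT_022","TRM TMT",4,3,"yes",,
"study2","TRM_TMT_023","TRM TMT",5,3,"yes",,
"study2","TRM_TMT_024","TRM TMT",6,3,"yes",,
"study2","TRM_TMT_025","TRM TMT",3,3,"yes",,
"study2","TRM_TMT_026","TRM TMT",4,3,"yes",,
"study2","TRM_TMT_027","TRM TMT",5,3,"yes",,
"study2","TRM_TMT_028","TRM TMT",6,3,"yes",,
"study2","TRM_TMT_029","TRM TMT",3,3,"yes",,
"study2","TRM_TMT_030","TRM TMT",4,3,"yes",,
"study2","TRM_TMT_031","TRM TMT",5,3,"yes",,
"study2","TRM_TMT_032","TRM TMT",6,3,"yes",,
"study2","TRM_TMT_033","TRM TMT",7,3,"yes",,
"study2","TRM_TMT_034","TRM TMT",8,4,"yes",,
"study2","TRM_TMT_035","TRM TMT",9,4,"yes",,
"study2","TRM_TMT_036","TRM TMT",10,4,"yes",,
"study2","TRM_TMT_037","TRM TMT",11,4,"yes",,
"study2","TRM_TMT_038","TRM TMT",12,4,"yes",,
"study2","TRM_TMT_039","TRM TMT",13,4,"yes",,
"study2","TRM_TMT_040","TRM TMT",14,4,"yes",,
"study2","TRM_TMT_041","TRM TMT",15,4,"yes",,
"study2","TRM_TMT_042","TRM TMT",16,4,"yes",,
"study2","TRM_TMT_043","TRM TMT",7,4,"yes",,
"study2","TRM_TMT_044","TRM TMT",8,4,"yes",,
"study2","TRM_TMT_045","TRM TMT",9,4,"yes",,
"study2","TRM_TMT_046","TRM TMT",10,4,"yes",,
"study2","TRM_TMT_047","TRM TMT",11,4,"yes",,
"study2","TRM_TMT_048","TRM TMT",12,4,"yes",,
"study2","TRM_TMT_049","TRM TMT",13,5,"yes",,
"study2","TRM_TMT_050","TRM TMT",14,5,"yes",,
"study2","TRM_TMT_051","TRM TMT",15,5,"yes",,
"study2","TRM_TMT_052","TRM TMT",16,5,"yes",,
"study2","TRM_TMT_053","TRM TMT",7,5,"yes",,
"study2","TRM_TMT_054","TRM TMT",8,5,"yes",,
"study2","TRM_TMT_055","TRM TMT",9,5,"yes",,
"study2","TRM_TMT_056","TRM TMT",10,5,"yes",,
"study2","TRM_TMT_057","TRM TMT",11,5,"yes",,
"study2","TRM_TMT_058","TRM TMT",12,5,"yes",,
"study2","TRM_TMT_059","TRM TMT",13,5,"yes",,
"study2","TRM_TMT_060","TRM TMT",14,5,"yes",,
"study2","TRM_TMT_061","TRM TMT",15,5,"yes",,
"study2","TRM_TMT_062","TRM TMT",16,5,"yes",,
"study2","TRM_TMT_063","TRM TMT",7,5,"yes",,
"study2","TRM_TMT_064","TRM TMT",8,5,"yes",,
"study2","TRM_TMT_065","TRM TMT",9,5,"yes",,
"study2","TRM_TMT_066","TRM TMT",10,5,"yes",,
"study2","TRM_TMT_067","TRM TMT",11,5,"yes",,
"study2","TRM_TMT_068","TRM TMT",12,5,"yes",,
"study2","TRM_LQD_001","TRM LQD",3,1,"no",,
"study2","TRM_LQD_002","TRM LQD",4,1,"no",,
"study2","TRM_LQD_003","TRM LQD",5,1,"no",,
"study2","TRM_LQD_004","TRM LQD",6,1,"no",,
"study2","TRM_LQD_005","TRM LQD",3,1,"no",,
"study2","TRM_LQD_006","TRM LQD",4,1,"no",,
"study2","TRM_LQD_007","TRM LQD",5,1,"no",,
"study2","TRM_LQD_008","TRM LQD",6,1,"no",,
"study2","TRM_LQD_009","TRM LQD",3,1,"no",,
"study2","TRM_LQD_010","TRM LQD",4,1,"no",,
"study2","TRM_LQD_011","TRM LQD",5,1,"no",,
"study2","TRM_LQD_012","TRM LQD",6,1,"no",,
"study2","TRM_LQD_013","TRM LQD",3,1,"no",,
"study2","TRM_LQD_014","TRM LQD",4,1,"no",,
"study2","TRM_LQD_015","TRM LQD",5,1,"no",,
"study2","TRM_LQD_016","TRM LQD",6,1,"no",,
"study2","TRM_LQD_017","TRM LQD",3,1,"no",,
"study2","TRM_LQD_018","TRM LQD",4,1,"no",,
"study2","TRM_LQD_019","TRM LQD",5,1,"no",,
"study2","TRM_LQD_020","TRM LQD",6,1,"no",,
"study2","TRM_LQD_021","TRM LQD",3,1,"no",,
"study2","TRM_LQD_022","TRM LQD",4,1,"no",,
"study2","TRM_LQD_023","TRM LQD",5,1,"no",,
"study2","TRM_LQD_024","TRM LQD",6,1,"no",,
"study2","TRM_LQD_025","TRM LQD",3,1,"no",,
"study2","TRM_LQD_026","TRM LQD",4,1,"no",,
"study2","TRM_LQD_027","TRM LQD",5,1,"no",,
"study2","TRM_LQD_028","TRM LQD",6,1,"no",,
"study2","TRM_LQD_029","TRM LQD",3,1,"no",,
"study2","TRM_LQD_030","TRM LQD",4,1,"no",,
"study2","TRM_LQD_031","TRM LQD",5,1,"no",,
"study2","TRM_LQD_032","TRM LQD",6,1,"no",,
"study2","TRM_LQD_033","TRM LQD",7,1,"no",,
"study2","TRM_LQD_034","TRM LQD",8,2,"no",,
"study2","TRM_LQD_035","TRM LQD",9,2,"no",,
"study2","TRM_LQD_036","TRM LQD",10,2,"no",,
"study2","TRM_LQD_037","TRM LQD",11,2,"no",,
"study2","TRM_LQD_038","TRM LQD",12,2,"no",,
"study2","TRM_LQD_039","TRM LQD",13,2,"no",,
"study2","TRM_LQD_040","TRM LQD",14,2,"no",,
"study2","TRM_LQD_041","TRM LQD",15,2,"no",,
"study2","TRM_LQD_042","TRM LQD",16,2,"no",,
"study2","TRM_LQD_043","TRM LQD",7,2,"no",,
"study2","TRM_LQD_044","TRM LQD",8,2,"no",,
"study2","TRM_LQD_045","TRM LQD",9,2,"no",,
"study2","TRM_LQD_046","TRM LQD",10,2,"no",,
"study2","TRM_LQD_047","TRM LQD",11,2,"no",,
"study2","TRM_LQD_048","TRM LQD",12,2,"yes",,
"study2","TRM_LQD_049","TRM LQD",13,2,"yes",,
"study2","TRM_LQD_050","TRM LQD",14,2,"yes",,
"study2","TRM_LQD_051","TRM LQD",15,2,"yes",,
"study2","TRM_LQD_052","TRM LQD",16,3,"yes",,
"study2","TRM_LQD_053","TRM LQD",7,3,"yes",,
"study2","TRM_LQD_054","TRM LQD",8,3,"yes",,
"study2","TRM_LQD_055","TRM LQD",9,3,"yes",,
"study2","TRM_LQD_056","TRM LQD",10,3,"yes",,
"study2","TRM_LQD_057","TRM LQD",11,3,"yes",,
"study2","TRM_LQD_058","TRM LQD",12,3,"yes",,
"study2","TRM_LQD_059","TRM LQD",13,3,"yes",,
"study2","TRM_LQD_060","TRM LQD",14,3,"yes",,
"study2","TRM_LQD_061","TRM LQD",15,3,"yes",,
"study2","TRM_LQD_062","TRM LQD",16,3,"yes",,
"study2","TRM_LQD_063","TRM LQD",7,4,"yes",,
"study2","TRM_LQD_064","TRM LQD",8,4,"yes",,
"study2","TRM_LQD_065","TRM LQD",9,4,"yes",,
"study2","TRM_LQD_066","TRM LQD",10,4,"yes",,
"study2","TRM_LQD_067","TRM LQD",11,4,"yes",,
"study2","TRM_LQD_068","TRM LQD",12,5,"yes",,
"study2","TRM_LQD_069","TRM LQD",13,5,"yes",,
"study2","TRM_LQD_070","TRM LQD",14,5,"yes",,
"study2","TRM_LQD_071","TRM LQD",15,5,"yes",,
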