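"study_id","participant_id","formulation_id","age_years","taste_score","willing_binary","willing_choice","willing_score"
"study1","MDZ_TMT_001","MDZ TMT",4,1,"no",,
"study1","MDZ_TMT_002","MDZ TMT",5,1,"no",,
"study1","MDZ_TMT_003","MDZ TMT",6,1,"no",,
"study1","MDZ_TMT_004","MDZ TMT",4,1,"no",,
"study1","MDZ_TMT_005","MDZ TMT",5,1,"no",,
"study1","MDZ_TMT_006","MDZ TMT",6,1,"no",,
"study1","MDZ_TMT_007","MDZ TMT",4,1,"no",,
"study1","MDZ_TMT_008","MDZ TMT",5,1,"no",,
"study1","MDZ_TMT_009","MDZ TMT",6,1,"no",,
"study1","MDZ_TMT_010","MDZ TMT",4,1,"no",,
"study1","MDZ_TMT_011","MDZ TMT",5,1,"no",,
"study1","MDZ_TMT_012","MDZ TMT",6,1,"no",,
"study1","MDZ_TMT_013","MDZ TMT",4,1,"no",,
"study1","MDZ_TMT_014","MDZ TMT",5,1,"no",,
"study1","MDZ_TMT_015","MDZ TMT",6,1,"no",,
"study1","MDZ_TMT_016","MDZ TMT",4,1,"no",,
"study1","MDZ_TMT_017","MDZ TMT",5,2,"no",,
"study1","MDZ_TMT_018","MDZ TMT",6,2,"no",,
"study1","MDZ_TMT_019","MDZ TMT",4,2,"no",,
"study1","MDZ_TMT_020","MDZ TMT",5,2,"no",,
"study1","MDZ_TMT_021","MDZ TMT",6,2,"no",,
"study1","MDZ_TMT_022","MDZ TMT",4,2,"no",,
"study1","MDZ_TMT_023","MDZ TMT",5,3,"no",,
"study1","MDZ_TMT_024","MDZ TMT",6,3,"no",,
"study1","MDZ_TMT_025","MDZ TMT",4,3,"no",,
"study1","MDZ_TMT_026","MDZ TMT",5,3,"no",,
"study1","MDZ_TMT_027","MDZ TMT",6,3,"no",,
"study1","MDZ_TMT_028","MDZ TMT",4,3,"no",,
"study1","MDZ_TMT_029","MDZ TMT",5,3,"no",,
"study1","MDZ_TMT_030","MDZ TMT",6,3,"yes",,
"study1","MDZ_TMT_031","MDZ TMT",4,3,"yes",,
"study1","MDZ_TMT_032","MDZ TMT",5,3,"yes",,
"study1","MDZ_TMT_033","MDZ TMT",6,3,"yes",,
"study1","MDZ_TMT_034","MDZ TMT",4,3,"yes",,
"study1","MDZ_TMT_035","MDZ TMT",5,3,"yes",,
"study1","MDZ_TMT_036","MDZ TMT",6,3,"yes",,
"study1","MDZ_TMT_037","MDZ TMT",4,3,"yes",,
"study1","MDZ_TMT_038","MDZ TMT",5,3,"yes",,
"study1","MDZ_TMT_039","MDZ TMT",7,4,"yes",,
"study1","MDZ_TMT_040","MDZ TMT",8,4,"yes",,
"study1","MDZ_TMT_041","MDZ TMT",9,4,"yes",,
"study1","MDZ_TMT_042","MDZ TMT",10,4,"yes",,
"study1","MDZ_TMT_043","MDZ TMT",11,4,"yes",,
"study1","MDZ_TMT_044","MDZ TMT",12,4,"yes",,
"study1","MDZ_TMT_045","MDZ TMT",13,4,"yes",,
"study1","MDZ_TMT_046","MDZ TMT",14,4,"yes",,
"study1","MDZ_TMT_047","MDZ TMT",15,4,"yes",,
"study1","MDZ_TMT_048","MDZ TMT",16,4,"yes",,
"study1","MDZ_TMT_049","MDZ TMT",7,4,"yes",,
"study1","MDZ_TMT_050","MDZ TMT",8,4,"yes",,
"study1","MDZ_TMT_051","MDZ TMT",9,4,"yes",,
"study1","MDZ_TMT_052","MDZ TMT",10,4,"yes",,
"study1","MDZ_TMT_053","MDZ TMT",11,4,"yes",,
"study1","MDZ_TMT_054","MDZ TMT",12,4,"yes",,
"study1","MDZ_TMT_055","MDZ TMT",13,4,"yes",,
"study1","MDZ_TMT_056","MDZ TMT",14,4,"yes",,
"study1","MDZ_TMT_057","MDZ TMT",15,4,"yes",,
"study1","MDZ_TMT_058","MDZ TMT",16,4,"yes",,
"study1","MDZ_TMT_059","MDZ TMT",7,5,"yes",,
"study1","MDZ_TMT_060","MDZ TMT",8,5,"yes",,
"study1","MDZ_TMT_061","MDZ TMT",9,5,"yes",,
"study1","MDZ_TMT_062","MDZ TMT",10,5,"yes",,
"study1","MDZ_TMT_063","MDZ TMT",11,5,"yes",,
"study1","MDZ_TMT_064","MDZ TMT",12,5,"yes",,
"study1","MDZ_TMT_065","MDZ TMT",13,5,"yes",,
"study1","MDZ_TMT_066","MDZ TMT",14,5,"yes",,
"study1","MDZ_TMT_067","MDZ TMT",15,5,"yes",,
"study1","MDZ_TMT_068","MDZ TMT",16,5,"yes",,
"study1","MDZ_TMT_069","MDZ TMT",7,5,"yes",,
"study1","MDZ_TMT_070","MDZ TMT",8,5,"yes",,
"study1","MDZ_TMT_071","MDZ TMT",9,5,"yes",,
"study1","MDZ_TMT_072","MDZ TMT",10,5,"yes",,
"study1","MDZ_TMT_073","MDZ TMT",11,5,"yes",,
"study1","MDZ_TMT_074","MDZ TMT",12,5,"yes",,
"study1","MDZ_TMT_extra","MDZ TMT",5,,,,
"study1","MDZ_LQD_001","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_002","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_003","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_004","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_005","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_006","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_007","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_008","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_009","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_010","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_011","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_012","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_013","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_014","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_015","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_016","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_017","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_018","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_019","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_020","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_021","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_022","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_023","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_024","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_025","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_026","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_027","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_028","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_029","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_030","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_031","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_032","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_033","MDZ LQD",6,1,"no",,
"study1","MDZ_LQD_034","MDZ LQD",4,1,"no",,
"study1","MDZ_LQD_035","MDZ LQD",5,1,"no",,
"study1","MDZ_LQD_036","MDZ LQD",7,1,"no",,
"study1","MDZ_LQD_037","MDZ LQD",8,1,"no",,
"study1","MDZ_LQD_038","MDZ LQD",9,1,"no",,
"study1","MDZ_LQD_039","MDZ LQD",10,2,"no",,
"study1","MDZ_LQD_040","MDZ LQD",11,2,"no",,
"study1","MDZ_LQD_041","MDZ LQD",12,2,"no",,
"study1","MDZ_LQD_042","MDZ LQD",13,2,"no",,
"study1","MDZ_LQD_043","MDZ LQD",14,2,"no",,
"study1","MDZ_LQD_044","MDZ LQD",15,2,"no",,
"study1","MDZ_LQD_045","MDZ LQD",16,2,"yes",,
"study1","MDZ_LQD_046","MDZ LQD",7,2,"yes",,
"study1","MDZ_LQD_047","MDZ LQD",8,2,"yes",,
"study1","MDZ_LQD_048","MDZ LQD",9,2,"yes",,
"study1","MDZ_LQD_049","MDZ LQD",10,2,"yes",,
"study1","MDZ_LQD_050","MDZ LQD",11,2,"yes",,
"study1","MDZ_LQD_051","MDZ LQD",12,2,"yes",,
"study1","MDZ_LQD_052","MDZ LQD",13,2,"yes",,
"study1","MDZ_LQD_053","MDZ LQD",14,2,"yes",,
"study1","MDZ_LQD_054","MDZ LQD",15,2,"yes",,
"study1","MDZ_LQD_055","MDZ LQD",16,2,"yes",,
"study1","MDZ_LQD_056","MDZ LQD",7,3,"yes",,
"study1","MDZ_LQD_057","MDZ LQD",8,3,"yes",,
"study1","MDZ_LQD_058","MDZ LQD",9,3,"yes",,
"study1","MDZ_LQD_059","MDZ LQD",10,3,"yes",,
"study1","MDZ_LQD_060","MDZ LQD",11,3,"yes",,
"study1","MDZ_LQD_061","MDZ LQD",12,3,"yes",,
"study1","MDZ_LQD_062","MDZ LQD",13,3,"yes",,
"study1","MDZ_LQD_063","MDZ LQD",14,3,"yes",,
"study1","MDZ_LQD_064","MDZ LQD",15,3,"yes",,
"study1","MDZ_LQD_065","MDZ LQD",16,3,"yes",,
"study1","MDZ_LQD_066","MDZ LQD",7,3,"yes",,
"study1","MDZ_LQD_067","MDZ LQD",8,3,"yes",,
"study1","MDZ_LQD_068","MDZ LQD",9,4,"yes",,
"study1","MDZ_LQD_069","MDZ LQD",10,4,"yes",,
"study1","MDZ_LQD_070","MDZ LQD",11,4,"yes",,
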