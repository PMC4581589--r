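person_id,arm,center,regimen,base_cd4,base_cd4_cat,bmi_low,hb_low,who4_wk24_48,cotrim_prev,stratum,k,on_first_line,switched,switch_day,cd4_measured,cd4_obs,cd4_true,ev_who3,ev_who3_day,ev_cand,ev_cand_day,ev_who4,ev_who4_day,ev_tbp,ev_tbp_day,ev_tbe,ev_tbe_day,miss_visits,miss_doses,death,ltfu,substudy,substudy_entry
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,0,1,0,,1,529,485,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,1,1,0,,0,,324,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,2,1,0,,0,,306,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,3,1,0,,1,301,307,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,4,1,0,,0,,319,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,5,1,0,,0,,324,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,6,1,0,,1,282,314,1,17,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,7,1,0,,0,,317,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,8,1,0,,0,,324,0,,0,,0,,0,,0,,0,0,0,0,none,
1,CDM,1,2,529,>=200,0,0,0,0,1:CDM,9,1,0,,1,372,324,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,0,1,0,,1,91,102,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,1,1,0,,0,,97,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,2,1,0,,0,,91,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,3,1,0,,1,92,82,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,4,1,0,,0,,79,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,5,1,0,,0,,68,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,6,1,0,,1,76,53,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,7,1,0,,0,,60,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,8,1,0,,0,,51,0,,0,,0,,0,,0,,0,0,0,0,none,
2,LCM,1,1,91,<100,0,0,0,1,1:LCM,9,1,0,,1,38,50,0,,0,,0,,0,,0,,0,0,0,0,none,
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,0,1,0,,1,134,140,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,1,1,0,,0,,141,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,2,1,0,,0,,140,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,3,1,0,,1,130,145,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,4,1,0,,0,,152,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,5,1,0,,0,,128,0,,0,,0,,0,,0,,0,1,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,6,1,0,,1,119,124,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,7,1,0,,0,,117,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,8,1,0,,0,,114,0,,0,,0,,0,,0,,0,0,0,0,CT,1
3,CDM,1,2,134,100-199,0,0,0,1,1:CDM,9,1,0,,1,131,118,0,,0,,0,,0,,0,,0,0,0,0,CT,1
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,0,1,0,,1,138,164,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,1,1,0,,0,,168,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,2,1,0,,0,,174,0,,0,,0,,0,,0,,0,1,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,3,1,0,,1,146,178,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,4,1,0,,0,,191,0,,0,,0,,0,,0,,0,1,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,5,1,0,,0,,179,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,6,1,0,,1,164,185,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,7,1,0,,0,,190,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,8,1,0,,0,,197,0,,0,,0,,0,,0,,0,0,0,0,none,
4,LCM,3,1,138,100-199,0,0,0,1,3:LCM,9,1,0,,1,201,200,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,0,1,0,,1,112,118,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,1,1,0,,0,,133,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,2,1,0,,0,,138,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,3,1,0,,1,153,130,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,4,1,0,,0,,122,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,5,1,0,,0,,121,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,6,1,0,,1,140,120,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,7,1,0,,0,,120,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,8,1,0,,0,,105,0,,0,,0,,0,,0,,0,0,0,0,none,
5,CDM,2,3,112,100-199,0,0,0,1,2:CDM,9,1,0,,1,108,112,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,0,1,0,,1,113,120,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,1,1,0,,0,,127,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,2,1,0,,0,,127,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,3,1,0,,1,148,125,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,4,1,0,,0,,121,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,5,1,0,,0,,119,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,6,1,0,,1,138,120,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,7,1,0,,0,,124,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,8,1,0,,0,,120,0,,0,,0,,0,,0,,0,0,0,0,none,
6,LCM,2,1,113,100-199,0,0,0,1,2:LCM,9,1,0,,1,142,138,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,0,1,0,,1,318,281,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,1,1,0,,0,,288,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,2,1,0,,0,,275,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,3,1,0,,1,289,290,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,4,1,0,,0,,296,0,,0,,0,,0,,0,,0,1,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,5,1,0,,0,,290,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,6,1,0,,1,322,287,0,,0,,0,,0,,0,,0,1,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,7,1,0,,0,,287,0,,0,,0,,0,,0,,0,0,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,8,1,0,,0,,322,0,,0,,0,,0,,0,,0,1,0,0,none,
7,CDM,3,1,318,>=200,0,0,0,1,3:CDM,9,1,0,,1,305,299,0,,0,,0,,0,,0,,0,0,0,0,none,
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,0,1,0,,1,204,190,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,1,1,0,,0,,177,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,2,1,0,,0,,181,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,3,1,0,,1,181,173,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,4,1,0,,0,,162,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,5,1,0,,0,,157,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,6,1,0,,1,192,154,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,7,1,0,,0,,169,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,8,1,0,,0,,167,0,,0,,0,,0,,0,,0,0,0,0,CT,1
8,LCM,2,2,204,>=200,0,0,0,0,2:LCM,9,1,0,,1,154,172,0,,0,,0,,0,,0,,0,1,0,0,CT,1
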