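study_id,label,population,outcome,adjusted,stratum,cat_lower,cat_upper,cat_point,cases,total,rr,ci_lower,ci_upper,is_reference,per_unit_rr,per_unit_lo,per_unit_hi,cat_label,ami_cohort,auxiliary,study_cases,study_total
halkos,Halkos,mixed,POAF_CABG,TRUE,,,,,,,,,,FALSE,0.89,0.8,0.98,,FALSE,FALSE,549,3089
matsuura,Matsuura,diabetes_or_IGT,POAF_CABG,FALSE,,,,,,,,,,FALSE,0.87,0.64,1.19,,FALSE,FALSE,26,101
tsuruta,Tsuruta,diabetes_or_IGT,POAF_CABG,FALSE,,,6.5,,,,1,,,TRUE,,,,,FALSE,FALSE,36,305
tsuruta,Tsuruta,diabetes_or_IGT,POAF_CABG,FALSE,,6.5,7.5,,,,0.89,0.36,2.21,FALSE,,,,,FALSE,FALSE,36,305
tsuruta,Tsuruta,diabetes_or_IGT,POAF_CABG,FALSE,,7.5,,,,,1.25,0.58,2.71,FALSE,,,,,FALSE,FALSE,36,305
tsuruta,Tsuruta,diabetes_or_IGT,POAF_CABG,FALSE,,,,,,,,,,FALSE,1.12,0.76,1.65,,FALSE,FALSE,36,305
kinoshita,Kinoshita,mixed,POAF_CABG,TRUE,,3.8,5.6,,,,1,,,TRUE,,,,,FALSE,FALSE,159,805
kinoshita,Kinoshita,mixed,POAF_CABG,TRUE,,6.8,11.4,,,,0.55,0.35,0.88,FALSE,,,,,FALSE,FALSE,159,805
kinoshita,Kinoshita,mixed,POAF_CABG,TRUE,,,,,,,,,,FALSE,0.78,0.63,0.95,,FALSE,FALSE,159,805
surer,Surer,mixed,POAF_CABG,FALSE,,,,,,,,,,FALSE,3.92,1.92,7.99,,FALSE,FALSE,12,72
abbaszadeh,Abbaszadeh,diabetes_or_IGT,POAF_CABG,TRUE,,,,,,,,,,FALSE,1.06,0.93,1.2,,FALSE,FALSE,109,708
dublin,Dublin,no_known_diabetes,AF,TRUE,,,,5,,,1,,,TRUE,,,,,FALSE,FALSE,1410,3613
dublin,Dublin,no_known_diabetes,AF,TRUE,,,7,,,,1.06,0.74,1.51,FALSE,,,,,FALSE,FALSE,1410,3613
dublin,Dublin,no_known_diabetes,AF,TRUE,,7,8,,,,1.48,1.09,2.01,FALSE,,,,,FALSE,FALSE,1410,3613
dublin,Dublin,no_known_diabetes,AF,TRUE,,8,9,,,,1.46,1.02,2.08,FALSE,,,,,FALSE,FALSE,1410,3613
dublin,Dublin,no_known_diabetes,AF,TRUE,,9,,,,,1.96,1.22,3.14,FALSE,,,,,FALSE,FALSE,1410,3613
dublin,Dublin,no_known_diabetes,AF,TRUE,,,,,,,,,,FALSE,1.14,0.96,1.35,,FALSE,FALSE,1410,3613
huxley_nondm,Huxley,no_known_diabetes,AF,TRUE,non-DM,,,,,,,,,FALSE,1.05,0.96,1.15,,FALSE,FALSE,1311,13025
huxley_dm,Huxley,diabetes_or_IGT,AF,TRUE,DM,,,,,,,,,FALSE,1.13,1.07,1.2,,FALSE,FALSE,1311,13025
iguchi,Iguchi,no_known_diabetes,AF,TRUE,,,,,,,,,,FALSE,1.18,1.09,1.28,,FALSE,FALSE,1161,52448
turgut,Turgut,diabetes_or_IGT,AF,TRUE,,,,,,,,,,FALSE,1.87,0.747,3.014,,FALSE,FALSE,81,162
latini,Latini,diabetes_or_IGT,AF,TRUE,,,,,,,,,,FALSE,1.11,0.91,1.32,,FALSE,FALSE,613,8943
sandhu,Sandhu,no_known_diabetes,AF,TRUE,,,,,,,,,,FALSE,1.08,0.95,1.22,,FALSE,FALSE,1039,34720
sandhu_parox,Sandhu,no_known_diabetes,AF,TRUE,paroxysmal,,4.84,,,,1,,,TRUE,,,,,FALSE,TRUE,1039,34720
sandhu_parox,Sandhu,no_known_diabetes,AF,TRUE,paroxysmal,4.84,5,,,,0.9,0.69,1.17,FALSE,,,,,FALSE,TRUE,1039,34720
sandhu_parox,Sandhu,no_known_diabetes,AF,TRUE,paroxysmal,5,5.19,,,,0.99,0.77,1.27,FALSE,,,,,FALSE,TRUE,1039,34720
sandhu_parox,Sandhu,no_known_diabetes,AF,TRUE,paroxysmal,5.19,,,,,0.76,0.58,1,FALSE,,,,,FALSE,TRUE,1039,34720
sandhu_nonparox,Sandhu,no_known_diabetes,AF,TRUE,nonparoxysmal,,4.84,,,,1,,,TRUE,,,,,FALSE,TRUE,1039,34720
sandhu_nonparox,Sandhu,no_known_diabetes,AF,TRUE,nonparoxysmal,4.84,5,,,,1.3,0.85,1.97,FALSE,,,,,FALSE,TRUE,1039,34720
sandhu_nonparox,Sandhu,no_known_diabetes,AF,TRUE,nonparoxysmal,5,5.19,,,,1.43,0.96,2.15,FALSE,,,,,FALSE,TRUE,1039,34720
sandhu_nonparox,Sandhu,no_known_diabetes,AF,TRUE,nonparoxysmal,5.19,,,,,1.48,0.98,2.22,FALSE,,,,,FALSE,TRUE,1039,34720
blasco,Blasco,no_known_diabetes,AF,TRUE,,,5.5,,,,1,,,TRUE,,,,,TRUE,FALSE,12,601
blasco,Blasco,no_known_diabetes,AF,TRUE,,5.5,6.4,,,,1.68,0.64,4.39,FALSE,,,,,TRUE,FALSE,12,601
blasco,Blasco,no_known_diabetes,AF,TRUE,,6.4,,,,,29.74,10.79,81.94,FALSE,,,,,TRUE,FALSE,12,601
blasco,Blasco,no_known_diabetes,AF,TRUE,,,,,,,,,,FALSE,3.24,2.41,4.35,,TRUE,FALSE,12,601
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,,,,,,1,,,TRUE,,,,Control,FALSE,FALSE,1283,216852
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,,6.9,,,,1.03,0.84,1.27,FALSE,,,,,FALSE,FALSE,1283,216852
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,7,7.8,,,,1.11,0.97,1.28,FALSE,,,,,FALSE,FALSE,1283,216852
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,7.8,8.7,,,,1.28,1.12,1.47,FALSE,,,,,FALSE,FALSE,1283,216852
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,8.8,9.6,,,,1.4,1.15,1.69,FALSE,,,,,FALSE,FALSE,1283,216852
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,9.7,,,,,2.32,1.8,2.99,FALSE,,,,,FALSE,FALSE,1283,216852
dahlqvist,Dahlqvist,diabetes_or_IGT,AF,TRUE,,,,,,,,,,FALSE,1.14,1.06,1.24,,FALSE,FALSE,1283,216852
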