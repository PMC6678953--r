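record_id,data_year,age_years,sex,race,education,marital,resident_status,place_of_death,manner,underlying_cause,entity_conditions
r0000001,2012,90,male,white,secondary,widowed,nonlocal_us,nursing_home,natural,J849,J849
r0000002,2008,74,male,white,tertiary,widowed,local,hospital_inpatient,suicide,T509,T509
r0000003,2012,94,female,white,primary,married,nonlocal_us,home,,I509,I251 I509 J189 S720
r0000004,2016,81,female,white,primary,married,local,nursing_home,natural,I509,I251 I509 F199 C189
r0000005,2013,101,female,white,secondary,married,nonlocal_us,hospital_outpatient_er,natural,C80,D649 C509 C798 C80 T509
r0000006,2009,86,male,white,tertiary,widowed,local,hospital_inpatient,natural,I64,I619 I64 G819 E669 C61
r0000007,2008,92,female,white,secondary,widowed,local,hospital_inpatient,natural,A419,A419 N390 N19 R99
r0000008,2009,67,male,white,secondary,married,local,home,,J849,J849 F102 N189 C61
r0000009,2011,66,male,white,secondary,never_married,local,home,natural,C798,C509 C798 C80
r0000010,2016,53,female,black,secondary,married,nonlocal_us,home,homicide,T14,T14
r0000011,2011,71,male,white,secondary,married,local,hospital_inpatient,natural,C80,C798 C80
r0000012,2007,85,female,american_indian,secondary,divorced,local,home,natural,C798,J90 A419 E785 C509 C798 W74
r0000013,2010,88,male,white,tertiary,widowed,local,home,natural,I64,I619 I64 G819 S069
r0000014,2015,82,male,white,secondary,widowed,local,home,natural,I489,I251 I489 I509 I619 T509
r0000015,2015,70,male,white,secondary,never_married,nonlocal_us,home,homicide,T71,T14 T71
r0000016,2013,91,female,white,tertiary,widowed,local,nursing_home,natural,I489,I251 I489 I509 E785 L89 C189
r0000017,2015,101,male,black,primary,widowed,local,hospital_inpatient,natural,J449,J449 N189
r0000018,2010,73,female,white,secondary,widowed,local,home,natural,I509,I251 I489 I509
r0000019,2012,94,female,white,,widowed,local,home,natural,C61,G309 C61 R99
r0000020,2011,74,female,black,secondary,married,local,hospital_inpatient,natural,A419,A419 N19 T509
r0000021,2009,51,male,white,secondary,never_married,local,other,accident,W74,W74
r0000022,2013,86,male,white,primary,divorced,local,hospice,natural,A419,I509 A419 N19 C509 C80 R99
r0000023,2012,66,male,white,tertiary,married,local,hospital_outpatient_er,natural,C61,I619 J849 C61 S720
r0000024,2012,91,male,white,tertiary,widowed,local,home,natural,N189,F102 E149 N189 C509 C798 C189 T14
r0000025,2015,81,male,white,tertiary,widowed,local,home,natural,J849,J849 E785 C61
r0000026,2006,72,male,black,secondary,never_married,local,home,natural,G819,I251 I489 I509 G819 T14
r0000027,2014,36,male,white,secondary,divorced,local,hospital_doa,homicide,W74,R570 W74
r0000028,2010,51,female,white,tertiary,never_married,nonlocal_us,hospital_inpatient,,T14,T14
r0000029,2009,94,male,black,secondary,widowed,nonlocal_us,nursing_home,natural,J849,J849 C61
r0000030,2010,50,male,white,secondary,never_married,nonlocal_us,hospital_inpatient,accident,T509,T509
r0000031,2015,94,female,black,tertiary,divorced,local,hospital_inpatient,natural,G309,J690 G309 L89 C189 C80 S720
r0000032,2010,98,female,white,tertiary,widowed,local,hospital_inpatient,,N19,I251 J690 A419 N390 N19
r0000033,2006,55,male,black,secondary,married,local,home,natural,C80,G309 L89 C509 C798 C80
r0000034,2016,69,female,black,secondary,married,local,home,,C80,C509 C80
r0000035,2015,38,male,white,tertiary,divorced,local,hospital_inpatient,accident,T509,T509
r0000036,2006,74,male,white,secondary,widowed,local,nursing_home,natural,C859,C61 C859 C189
r0000037,2016,49,male,white,secondary,divorced,nonlocal_us,hospital_outpatient_er,homicide,T14,T14
r0000038,2011,67,female,white,secondary,divorced,nonlocal_us,home,natural,I64,I619 I64 A419 N189
r0000039,2007,53,male,white,tertiary,married,local,hospital_inpatient,natural,C189,I219 I509 D649 C859 C189
r0000040,2011,42,male,white,secondary,widowed,local,hospital_inpatient,suicide,T14,T14 T71
r0000041,2012,105,male,white,secondary,widowed,local,hospital_inpatient,natural,I119,I10 I119 I219 G819 N390 E785 N189
r0000042,2008,60,female,asian_pacific,secondary,widowed,nonlocal_us,hospital_inpatient,accident,T509,T509
r0000043,2015,71,male,white,tertiary,married,local,nursing_home,,I64,I619 I64 J690 D649
r0000044,2006,64,male,white,tertiary,married,local,home,homicide,T14,T14
r0000045,2016,84,female,white,tertiary,widowed,local,other,natural,E149,E149 E669 N189 C61
r0000046,2015,98,female,white,tertiary,widowed,local,other,natural,A419,A419 N390 N19
r0000047,2014,94,female,white,secondary,divorced,local,other,natural,I509,I509 A419
r0000048,2006,69,female,white,primary,widowed,local,nursing_home,natural,I10,I10 I119 J189 E785
r0000049,2016,77,female,black,tertiary,married,local,home,natural,F179,F179 N390 N19 C349 K746
r0000050,2012,79,female,white,tertiary,widowed,local,nursing_home,natural,K746,C509 K746 K922
r0000051,2010,100,female,white,primary,widowed,local,hospital_inpatient,natural,J449,J449 J189 J969
r0000052,2010,109,female,white,secondary,never_married,local,home,natural,G309,J690 G309 F199 L89
r0000053,2016,82,male,white,secondary,widowed,local,hospital_inpatient,natural,I619,I619 I64 J189 F102
r0000054,2011,38,female,white,tertiary,never_married,local,hospital_doa,accident,W74,W74
r0000055,2014,75,male,white,secondary,never_married,nonlocal_us,home,natural,I469,I469
r0000056,2008,46,female,white,secondary,married,local,nursing_home,natural,T509,T509
r0000057,2008,70,female,white,primary,widowed,local,hospice,natural,C80,I64 C509 C798 C80
r0000058,2013,70,female,black,secondary,widowed,nonlocal_us,hospital_inpatient,natural,C509,G309 C509 C189 C80
r0000059,2014,61,male,white,secondary,married,nonlocal_us,hospital_doa,suicide,T509,T509
r0000060,2010,87,male,white,secondary,divorced,nonlocal_us,hospital_inpatient,natural,A419,A419 E669 N19 C189
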