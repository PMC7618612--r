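stratum_group,stratum,n_total,n_pincer,n_rhoa,n_pincer_rhoa
age,40-50,1534,307,40,16
age,51-60,6180,1363,149,47
age,61-70,7557,2056,110,26
age,70+,3664,1168,53,12
bmi,<25,6094,1600,125,31
bmi,>=25,12841,3294,227,70
sex,male,5614,1352,82,19
sex,female,13321,3542,270,82
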