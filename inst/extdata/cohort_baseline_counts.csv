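cohort_id,n_hips,age_mean,age_sd,bmi_mean,bmi_sd,n_male,n_moderate_pincer,n_severe_pincer,n_incident_male,n_incident_female,population_type
CHECK,678,55.64,5.28,26.29,4.23,114,143,33,19,63,closed
Chingford,815,53.62,5.73,25.38,3.97,0,261,73,0,72,open
JoCo,633,59.25,8.72,29.60,6.02,282,149,35,18,36,open
MOST,1202,61.09,7.24,29.93,5.13,378,221,55,3,4,closed
OAI,4481,60.66,8.92,28.27,4.64,1860,1014,204,3,10,closed
RS-I,2719,65.21,6.33,26.15,3.45,1120,887,230,1,11,open
RS-II,1797,63.00,6.40,27.11,3.83,795,440,93,2,4,open
RS-III,2381,56.34,4.85,27.56,4.17,1065,522,108,36,17,open
SOF,4229,70.38,4.36,26.38,4.31,0,1257,290,0,53,closed
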