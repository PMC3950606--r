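group,male_rank,n_mating_periods,focal_hours,n_obs_days,n_urine_samples,n_females_mate_guarded,n_mg_days,mean_mg_period_days,mg_period_range_days,overall_mg_pct
Camp,alpha,2,668,147,45,5,41,3.9,1-18,27.4
Camp,beta,2,455,114,25,3,4,1,1-1,8.4
Ketambe Atas,alpha,1,185,68,27,3,30,4.9,1-13,40.2
Ketambe Atas,beta,1,111,48,19,2,27,9,3-33,53.9
Ketambe Bawa,alpha,2,388,122,32,8,49,3.7,1-10,36.9
Ketambe Bawa,beta,2,323,85,22,5,10,1.5,1-4,12.0
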