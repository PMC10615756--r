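probeset,gene_symbol,direction,discovery_method,discovery_percent,discovery_points,cfg_points,validation_stepwise,validation_p,validation_points,sig_state_sas4,sig_state_stai,sig_hosp_first_year,sig_hosp_all_future,published_cfe
205278_at,GAD1,increased,DE,62.3,4,11,FALSE,6.79E-01,0,,ALL;gender;gender_dx,gender_dx,ALL;gender;gender_dx,22
209869_at,ADRA2A,increased,AP,50,4,4,FALSE,9.07E-01,0,gender_dx,gender;gender_dx,ALL;gender;gender_dx,ALL;gender;gender_dx,17
219764_at,FZD10,increased,DE,53.2,4,2,TRUE,3.57E-01,2,,ALL;gender;gender_dx,ALL;gender;gender_dx,ALL;gender;gender_dx,17
210600_s_at,GRK4,increased,DE,81.8,6,0,TRUE,3.40E-01,2,gender_dx,gender;gender_dx,ALL;gender,ALL;gender;gender_dx,17
204311_at,ATP1B2,increased,DE,39,2,4,TRUE,1.65E-01,2,gender_dx,gender;gender_dx,gender;gender_dx,ALL;gender;gender_dx,16
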