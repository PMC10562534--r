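name,base,low,high,psa_class,units
body_weight,70,52.5,87.5,normal,kg
bsa,1.86,1.40,2.33,normal,m2
discount_rate,0.03,0,0.08,uniform,per_year
p_surgery_mortality_30d,0.023,0.017,0.029,beta,probability
cost_pembrolizumab_mg,54.81,41.11,68.51,gamma,USD_per_mg
cost_cisplatin_mg,0.32,0.24,0.40,gamma,USD_per_mg
cost_pemetrexed_mg,6.45,4.84,8.06,gamma,USD_per_mg
cost_gemcitabine_mg,0.02,0.01,0.03,gamma,USD_per_mg
cost_radiotherapy_event,16335.11,12251.33,20418.89,gamma,USD
cost_surgery_event,15687.42,11765.57,19609.28,gamma,USD
cost_infusion_first_hr,132.16,99.12,165.2,gamma,USD
cost_infusion_addl_hr,28.47,21.35,35.59,gamma,USD
cost_infusion_subseq_hr,65.06,48.80,81.33,gamma,USD
cost_bsc,3674.65,2755.99,4593.31,gamma,USD
cost_end_of_life,17909.24,13431.93,22386.55,gamma,USD
cost_follow_up,545.92,409.44,682.40,gamma,USD
cost_sae_anemia,2024.32,1518.24,2530.40,gamma,USD
cost_sae_neutropenia,1276.52,957.39,1595.65,gamma,USD
cost_sae_thrombocytopenia,2220.14,1665.11,2775.18,gamma,USD
utility_radiotherapy,0.79,0.71,0.87,beta,utility
utility_surgery,0.73,0.66,0.80,beta,utility
utility_pd,0.65,0.59,0.72,beta,utility
utility_pf,0.75,0.68,0.83,beta,utility
disutility_anemia,0.25,0.23,0.28,beta,utility
disutility_neutropenia,0.07,0.06,0.08,beta,utility
disutility_thrombocytopenia,0.35,0.32,0.39,beta,utility
risk_anemia_pem,0.07,0.05,0.09,beta,probability
risk_neutropenia_pem,0.21,0.16,0.26,beta,probability
risk_thrombocytopenia_pem,0.05,0.04,0.06,beta,probability
risk_anemia_placebo,0.06,0.05,0.08,beta,probability
risk_neutropenia_placebo,0.20,0.15,0.25,beta,probability
risk_thrombocytopenia_placebo,0.06,0.05,0.08,beta,probability
prop_local_therapy_pem,0.821,0.61575,1,beta,probability
prop_local_therapy_placebo,0.793,0.59475,0.99125,beta,probability
prop_adjuvant_uptake,0.889,0.66675,1,beta,probability
prop_surgery_among_local,0.92,0.69,1,beta,probability
prop_nonsquamous,0.57,0.4275,0.7125,beta,probability
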