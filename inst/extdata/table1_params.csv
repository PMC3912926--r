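name,role,value,dist,moment_a,moment_b,source
cost_discount_rate,rate,0.04,fixed,,,Dutch pharmacoeconomic guideline
effect_discount_rate,rate,0.015,fixed,,,Dutch pharmacoeconomic guideline
abi_test_cost,cost,74,beta_pert,55.7,92.8,academic hospital tariff
cost_pad_treatment_annual,cost,2369,gamma,325.09,7.29,annual care cost of an average PAD patient
cost_aspirin_annual,cost,10,fixed,,,Dutch medicine cost listing
cost_clopidogrel_annual,cost,19,fixed,,,Dutch medicine cost listing
cost_amputation,cost,14343,beta_pert,10683,17804,Dutch costing study
cost_mi_first_year,cost,25328,gamma,100,253.27,Dutch costing study
cost_mi_subsequent_annual,cost,3584,gamma,99.92,35.86,Dutch costing study
cost_stroke_first_year,cost,27964,gamma,99.99,279.66,Dutch costing study
cost_stroke_subsequent_annual,cost,10646,gamma,99.99,106.47,Dutch costing study
cost_bleed,cost,3457,gamma,99.87,34.61,Dutch costing study
abi_sensitivity,accuracy,0.90,beta_pert,0.68,1,ABI diagnostic accuracy review
abi_specificity,accuracy,0.95,beta_pert,0.71,1,ABI diagnostic accuracy review
pad_prevalence,probability,0.184,beta,1372,6082,high-risk primary-care population
pad_incidence_55_64,probability,0.005,beta,0.5,99.5,synthetic moments (mean-pinned; ESS 100)
pad_incidence_65_74,probability,0.007,beta,0.7,99.3,synthetic moments (mean-pinned; ESS 100)
pad_incidence_75_84,probability,0.008,beta,0.8,99.2,synthetic moments (mean-pinned; ESS 100)
pad_incidence_85plus,probability,0.010,beta,1,99,synthetic moments (mean-pinned; ESS 100)
p_amputation_no_pad,probability,0.003,beta,32,11734,REACH registry
p_mi_no_pad,probability,0.008,beta,89,11677,REACH registry
p_stroke_no_pad,probability,0.008,beta,94,11672,REACH registry
p_amputation_pad,probability,0.016,beta,140,8441,REACH registry
p_mi_pad,probability,0.013,beta,111,8470,REACH registry
p_stroke_pad,probability,0.019,beta,165,8416,REACH registry
p_symptomatic_pad,probability,0.3,beta,138,320,claudication fraction among PAD
rr_aspirin,relative_risk,0.78,beta,25.45,7.2,antiplatelet meta-analysis
p_bleed_aspirin,probability,0.026,beta,255,9311,CAPRIE trial
rr_clopidogrel,relative_risk,0.616,beta,61.6,38.4,synthetic moments (mean-pinned; ESS 100)
p_bleed_clopidogrel,probability,0.020,beta,191,9386,CAPRIE trial
p_death_pad,probability,0.037,beta,323,8258,REACH registry
p_death_post_amputation,probability,0.155,beta,4297,21281,amputation outcome study
p_death_post_mi,probability,0.028,beta,521,17492,REACH registry
p_death_post_stroke,probability,0.031,beta,1212,37390,REACH registry
utility_pad,utility,0.652,beta,0.8,0.4,EQ-5D population catalogue
utility_post_amputation,utility,0.45,beta,210.8,257.7,standard-gamble amputee study
utility_post_mi,utility,0.671,beta,69.3,34,EQ-5D population catalogue
utility_post_stroke,utility,0.519,beta,2.7,2.5,EQ-5D population catalogue
utility_post_bleed,utility,0.627,beta,405.6,241.13,EQ-5D population catalogue
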