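name,family,mean,low95,high95,description
p_tnbc_all,beta,0.039,0.034,0.041,Annual TNBC-specific death probability (all stages)
p_tnbc_localized,beta,0.017,0.012,0.019,Annual TNBC-specific death probability (localized)
p_tnbc_regional,beta,0.066,0.058,0.077,Annual TNBC-specific death probability (regional)
p_tnbc_distant,beta,0.290,0.204,0.369,Annual TNBC-specific death probability (distant)
hr_all,lognormal,0.66,0.47,0.91,Hazard ratio for TNBC death with any beta-blocker use (all stages)
hr_localized,lognormal,0.86,0.48,1.56,Hazard ratio for TNBC death (localized)
hr_regional,lognormal,0.54,0.34,0.86,Hazard ratio for TNBC death (regional)
hr_distant,lognormal,0.69,0.24,2.04,Hazard ratio for TNBC death (distant)
u_population_average,beta,0.90,0.89,0.91,Population-average utility for evLY valuation
u_decrement_tnbc,beta,-0.024,-0.03,-0.02,Utility decrement while alive with TNBC
u_decrement_terminal,normal,-0.110,-0.27,0.05,Extra utility decrement in the TNBC death cycle
c_drug_propranolol,gamma,113.95,91.62,136.29,Annual cost of propranolol 40 mg twice daily (AUD 2022)
c_drug_carvedilol,gamma,258.18,207.57,308.78,Annual cost of carvedilol 12.5 mg twice daily (AUD 2022)
c_mgmt_y1,gamma,42409,34097,50721,BC management cost 0-1 years since diagnosis (AUD 2022)
c_mgmt_y2,gamma,8745,7031,10459,BC management cost 1-2 years since diagnosis (AUD 2022)
c_mgmt_y3,gamma,3487,2804,4170,BC management cost 2-3 years since diagnosis (AUD 2022)
c_mgmt_y4,gamma,3595,2890,4300,BC management cost 3-4 years since diagnosis (AUD 2022)
c_mgmt_y5,gamma,2839,2282,3395,BC management cost 4-5 years since diagnosis (AUD 2022)
c_terminal_tnbc,gamma,44327,35639,53015,Terminal-phase cost per TNBC death (AUD 2022)
c_death_other,gamma,5844,4698,6989,Cost per non-TNBC death (AUD 2022)
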