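band,medc_min,medc_max,grade,hr_lo_max,gain_min,milestone_months,milestone_increase_min
short,0,12,2,0.70,1.5,NA,NA
short,0,12,3,0.65,2.5,NA,NA
short,0,12,4,0.65,3,24,0.10
long,12,Inf,2,0.75,1.5,NA,NA
long,12,Inf,3,0.70,3,NA,NA
long,12,Inf,4,0.70,5,36,0.10
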