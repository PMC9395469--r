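# Published per-100,000 cost-effectiveness results of Dutch LDCT lung cancer
# screening scenarios (discounted costs in EUR, discounted QALYs), used as
# input data for arithmetic-consistency checks. The *_printed columns carry
# the values as printed in the source table; extended_dominated_printed
# flags the rows marked there as excluded by extended dominance.
scenario,cost,qaly,icer_printed,cost_vs_ref_printed,qaly_gained_printed,cer_printed,extended_dominated_printed
no screening,18475224,2520.9,NA,NA,NA,NA,0
70 years and older,19931407,2608.7,NA,1456183,87.8,16594,1
60-70 years,22264907,2770.5,NA,3789683,249.6,15182,1
50-60 years,23143766,2852.2,14094,4668542,331.2,14094,0
60 years and older,23721090,2858.3,NA,5245866,337.4,15549,1
50-70 years,26933449,3101.8,15182,8458225,580.9,14561,0
50 years and older,28389632,3189.5,16594,9914408,668.6,14828,0
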