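term,estimate,std_error,t_stat,p_value
intercept,0.047251,0.020211,2.337934,0.041485
nfall_freq,0.696391,0.188534,3.69372,0.004151
tot_num_abs,6.82e-08,1.62e-06,0.042112,0.967239
sit_freq,-0.00035,0.000178,-1.99592,0.073889
updrs_pull,-0.01573,0.006449,-2.43948,0.03488
alpha_8,-0.00391,0.001185,-3.30116,0.007998
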