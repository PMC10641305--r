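model,component,species,stream,value
random_effects,sigma2_t,,,0.60
random_effects,sigma2_s,,indian,0.64
random_effects,sigma2_s,,todd,1.08
random_effects,sigma2_j,BHC,,0.42
random_effects,sigma2_j,CRC,,0.44
random_effects,sigma2_j,STJ,,0.80
random_effects,sigma2_js,BHC,indian,1.33
random_effects,sigma2_js,CRC,indian,0.60
random_effects,sigma2_js,STJ,indian,1.50
random_effects,sigma2_js,BHC,todd,0.42
random_effects,sigma2_js,CRC,todd,1.28
random_effects,sigma2_js,STJ,todd,0.98
random_effects,icc,BHC,indian,0.58
random_effects,icc,CRC,indian,0.74
random_effects,icc,STJ,indian,0.59
random_effects,icc,BHC,todd,0.84
random_effects,icc,CRC,todd,0.66
random_effects,icc,STJ,todd,0.73
random_effects_plus_covariate,sigma2_t,,,0.41
random_effects_plus_covariate,sigma2_s,,indian,0.79
random_effects_plus_covariate,sigma2_s,,todd,0.81
random_effects_plus_covariate,sigma2_j,BHC,,0.33
random_effects_plus_covariate,sigma2_j,CRC,,0.49
random_effects_plus_covariate,sigma2_j,STJ,,0.78
random_effects_plus_covariate,sigma2_js,BHC,indian,1.14
random_effects_plus_covariate,sigma2_js,CRC,indian,0.89
random_effects_plus_covariate,sigma2_js,STJ,indian,1.37
random_effects_plus_covariate,sigma2_js,BHC,todd,0.36
random_effects_plus_covariate,sigma2_js,CRC,todd,1.09
random_effects_plus_covariate,sigma2_js,STJ,todd,1.07
random_effects_plus_covariate,sigma2_cov,,,0.60
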