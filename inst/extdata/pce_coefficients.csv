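group,term,value,source
white_female,ln_age,-29.799,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_age_sq,4.884,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_tc,13.540,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_age_ln_tc,-3.114,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_hdl,-13.578,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_age_ln_hdl,3.149,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_sbp_treated,2.019,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_sbp_untreated,1.957,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,smoker,7.574,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,ln_age_smoker,-1.665,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,diabetes,0.661,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,mean_lp,-29.18,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_female,s10,0.9665,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_age,17.114,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_tc,0.940,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_hdl,-18.920,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_age_ln_hdl,4.475,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_sbp_treated,29.291,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_age_ln_sbp_treated,-6.432,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_sbp_untreated,27.820,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,ln_age_ln_sbp_untreated,-6.087,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,smoker,0.691,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,diabetes,0.874,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,mean_lp,86.61,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_female,s10,0.9533,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_age,12.344,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_tc,11.853,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_age_ln_tc,-2.664,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_hdl,-7.990,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_age_ln_hdl,1.769,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_sbp_treated,1.797,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_sbp_untreated,1.764,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,smoker,7.837,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,ln_age_smoker,-1.795,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,diabetes,0.658,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,mean_lp,61.18,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
white_male,s10,0.9144,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,ln_age,2.469,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,ln_tc,0.302,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,ln_hdl,-0.307,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,ln_sbp_treated,1.916,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,ln_sbp_untreated,1.809,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,smoker,0.549,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,diabetes,0.645,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,mean_lp,19.54,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
black_male,s10,0.8954,"Goff et al. 2013 ACC/AHA risk assessment guideline, Appendix 7 Table A"
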