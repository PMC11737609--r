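component,FD1,FD2,FD3,ED,GY,AD,SD,PH,EH
sigma2_gca,0.04,0.03,0.07,0.06,0.22,1.29,1.32,95.77,58.34
sigma2_sca,0.00,0.04,0.04,0.04,0.27,0.37,0.45,80.88,36.65
sigma2_gca_env,0.01,0.04,0.06,0.04,0.17,0.03,0.07,5.80,0.21
sigma2_sca_env,0.15,0.07,0.15,0.04,0.39,0.17,0.56,107.72,52.87
sigma2_e,0.31,0.33,0.37,0.23,1.29,1.30,1.50,109.31,46.66
sigma2_a,0.08,0.05,0.14,0.11,0.45,2.58,2.63,191.53,116.69
sigma2_d,0.00,0.04,0.04,0.04,0.27,0.37,0.45,80.88,36.65
baker_ratio,1.00,0.60,0.78,0.75,0.62,0.87,0.85,0.70,0.76
sigma2_p,0.38,0.42,0.55,0.38,2.01,4.25,4.58,381.72,200.01
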