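comparison,variable,n_no,mean_no,sd_no,n_yes,mean_yes,sd_yes,p_value,effect_size
any,Age,24,54.08,11.82,120,58.33,10.89,0.060,0.383
any,Gender,24,0.38,0.48,120,0.43,0.49,0.327,0.102
any,BMI,24,29.19,4.47,120,32.37,6.04,0.003,0.545
any,AHI,24,32.15,27.66,120,32.34,25.79,0.488,0.007
any,HeartRate,24,74.43,21.39,120,67.09,14.44,0.063,0.464
any,t3_t1_mean,24,15.67,5.65,120,14.61,5.27,0.207,0.198
any,t4_t2_mean,24,14.77,4.93,120,13.07,4.78,0.069,0.353
any,delta_t_FP0_mean,24,51.73,8.77,120,50.01,10.01,0.204,0.175
any,delta_t_SpO2_mean,24,33.02,4.98,120,32.96,5.25,0.479,0.011
any,mean_delta_SpO2,24,6.93,4.11,120,6.45,2.99,0.296,0.150
any,mean_slope,24,0.24,0.15,120,0.23,0.12,0.381,0.080
hypertension,Age,65,53.96,10.95,79,60.65,10.40,0.000,0.626
hypertension,Gender,65,0.40,0.49,79,0.43,0.50,0.357,0.060
hypertension,BMI,65,30.12,5.76,79,33.26,5.70,0.001,0.546
hypertension,AHI,65,26.96,25.70,79,36.70,25.63,0.013,0.378
hypertension,HeartRate,65,70.52,17.25,79,66.50,14.74,0.072,0.252
hypertension,t3_t1_mean,65,14.19,5.44,79,15.29,5.22,0.112,0.206
hypertension,t4_t2_mean,65,12.89,4.84,79,13.73,4.82,0.151,0.173
hypertension,delta_t_FP0_mean,65,49.70,8.82,79,50.80,10.57,0.248,0.112
hypertension,delta_t_SpO2_mean,65,32.75,4.80,79,33.16,5.51,0.320,0.079
hypertension,mean_delta_SpO2,65,6.32,3.48,79,6.70,2.95,0.248,0.118
hypertension,mean_slope,65,0.23,0.13,79,0.24,0.13,0.395,0.077
diabetes,Age,79,60.06,10.45,65,55.62,11.32,0.008,0.408
diabetes,Gender,79,0.35,0.48,65,0.47,0.50,0.083,0.244
diabetes,BMI,79,33.22,6.08,65,30.71,5.56,0.006,0.428
diabetes,AHI,79,36.85,27.21,65,28.56,24.55,0.031,0.317
diabetes,HeartRate,79,66.58,16.52,65,69.74,15.50,0.123,0.196
diabetes,t3_t1_mean,79,14.23,5.08,65,15.24,5.52,0.133,0.190
diabetes,t4_t2_mean,79,12.76,4.23,65,13.84,5.25,0.090,0.228
diabetes,delta_t_FP0_mean,79,50.20,10.64,65,50.38,9.11,0.457,0.018
diabetes,delta_t_SpO2_mean,79,33.32,5.35,65,32.69,5.06,0.237,0.120
diabetes,mean_delta_SpO2,79,6.63,2.74,65,6.44,3.54,0.359,0.061
diabetes,mean_slope,79,0.24,0.13,65,0.23,0.12,0.357,0.079
asthma_copd,Age,79,57.28,10.68,65,57.91,11.53,0.367,0.057
asthma_copd,Gender,79,0.46,0.50,65,0.38,0.49,0.163,0.161
asthma_copd,BMI,79,31.80,6.02,65,31.88,5.85,0.466,0.013
asthma_copd,AHI,79,29.78,24.21,65,34.38,27.41,0.145,0.178
asthma_copd,HeartRate,79,68.21,12.20,65,68.40,18.62,0.472,0.012
asthma_copd,t3_t1_mean,79,14.90,5.51,65,14.70,5.21,0.416,0.037
asthma_copd,t4_t2_mean,79,13.27,5.18,65,13.42,4.55,0.427,0.030
asthma_copd,delta_t_FP0_mean,79,49.98,9.60,65,50.57,10.01,0.361,0.060
asthma_copd,delta_t_SpO2_mean,79,32.65,5.17,65,33.24,5.22,0.249,0.113
asthma_copd,mean_delta_SpO2,79,6.19,3.19,65,6.81,3.19,0.126,0.194
asthma_copd,mean_slope,79,0.23,0.12,65,0.24,0.13,0.234,0.080
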