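patient_id,Age,Gender,BMI,AHI,HeartRate,t3_t1_mean,t4_t2_mean,delta_t_FP0_mean,delta_t_SpO2_mean,mean_delta_SpO2,mean_slope
EX01,58,1,29.30,2.2,90.0,7.82,7.04,38.76,32.22,4.70,0.18
EX02,63,1,44.59,77.2,72.0,20.71,14.14,37.73,18.16,9.99,0.62
EX03,68,0,33.95,122.5,90.0,16.72,13.04,38.83,18.70,7.20,0.45
EX04,68,0,29.05,72.0,58.0,13.26,10.42,47.03,30.94,7.15,0.24
EX05,54,0,29.01,18.7,62.0,8.43,9.73,45.42,36.03,5.04,0.15
EX06,61,1,37.00,35.1,81.4,12.85,11.85,49.09,28.38,4.87,0.21
EX07,48,0,45.00,39.9,79.5,11.55,9.60,50.50,36.75,4.10,0.11
EX08,70,0,38.00,61.3,39.6,23.70,15.56,57.59,38.40,18.98,0.42
EX09,64,0,31.60,41.8,67.2,9.77,12.35,48.95,29.53,4.33,0.16
EX10,66,1,30.00,33.9,57.8,6.87,8.03,46.79,35.63,6.43,0.19
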