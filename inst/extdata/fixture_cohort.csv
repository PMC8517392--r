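# seed: 733339
# note: synthetic fixture
subject_id,group,age,male,smoking,bmi,bsa,sbp_mmhg,dbp_mmhg,heart_rate,tc,tg,hdl_c,ldl_c,hba1c,lvef,fpg,ppg_2h,duration_yr,pulse_pressure
NC0001,NC,43.7571,1,0,18.8997,1.6544,121.0649,84.1255,80.994,3.9517,0.8022,0.9909,2.7937,5.0997,65.0199,NA,NA,NA,36.9395
NC0002,NC,55.8205,1,0,20.9168,1.6977,116.4386,82.8661,58.9918,3.8594,1.9467,1.1498,2.9701,5.7662,66.2747,NA,NA,NA,33.5725
T2DM0001,T2DM,38.0594,1,0,25.4669,1.5187,124.9279,80.4026,59.2128,4.2149,2.8148,1.176,3.3378,8.4217,64.3449,8.5814,11.9413,0.5472,44.5252
T2DM0002,T2DM,38.6239,0,0,28.581,1.7386,121.7879,86.2183,73.54,2.8906,3.4293,1.3521,3.0092,7.2517,60.3375,8.64,10.7192,1.5772,35.5696
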