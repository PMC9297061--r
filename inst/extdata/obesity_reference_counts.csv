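table,feature,level,count,statistic,p_value
bmi_category,BMI,underweight,272,NA,NA
bmi_category,BMI,normal,287,NA,NA
bmi_category,BMI,overweight,580,NA,NA
bmi_category,BMI,obese_I,351,NA,NA
bmi_category,BMI,obese_II,297,NA,NA
bmi_category,BMI,obese_III,324,NA,NA
feature_count,FHWO,Yes,1442,NA,NA
feature_count,FHWO,No,102,NA,NA
feature_count,FAVC,Yes,1429,NA,NA
feature_count,FAVC,No,115,NA,NA
feature_count,SCC,Yes,38,NA,NA
feature_count,SCC,No,1506,NA,NA
feature_count,Gender,Female,720,NA,NA
feature_count,Gender,Male,824,NA,NA
feature_count,CALC,Frequently,51,NA,NA
feature_count,CALC,Sometimes,1079,NA,NA
feature_count,CALC,No,414,NA,NA
feature_count,CAEC,Always,17,NA,NA
feature_count,CAEC,Frequently,38,NA,NA
feature_count,CAEC,Sometimes,1451,NA,NA
feature_count,CAEC,No,38,NA,NA
feature_count,SMOKE,Yes,30,NA,NA
feature_count,SMOKE,No,1514,NA,NA
feature_count,MTRANS,Walking,18,NA,NA
feature_count,MTRANS,Bike,3,NA,NA
feature_count,MTRANS,Public_Transportation,1154,NA,NA
feature_count,MTRANS,Automobile,364,NA,NA
feature_count,MTRANS,Motorbike,5,NA,NA
covtest,FCVC,NA,NA,165.15,0.0000
covtest,NCP,NA,NA,3.40,0.0334
covtest,FAF,NA,NA,3.34,0.0353
covtest,CH2O,NA,NA,0.18,0.8328
covtest,TUE,NA,NA,0.15,0.8581
covtest,Age,NA,NA,0.02,0.9784
covtest,FHWO,NA,NA,17.77,0.0000
covtest,FAVC,NA,NA,12.34,0.0000
covtest,SCC,NA,NA,3.48,0.0309
covtest,Gender,NA,NA,2.41,0.0897
covtest,CALC,NA,NA,0.97,0.3793
covtest,CAEC,NA,NA,0.77,0.4629
covtest,SMOKE,NA,NA,0.75,0.4723
covtest,MTRANS,NA,NA,0.26,0.7674
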