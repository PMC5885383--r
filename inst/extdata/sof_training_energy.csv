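course,anthropometry_course,n,tdee,tdee_ci_low,tdee_ci_high,rmr,dit,aiee,pal,intake,intake_ci_low,intake_ci_high,balance,delta_bm,paf,model_a,model_b
Combat Dive School,Combat Dive School,11,4567,4332,4803,1748,457,2363,2.61,NA,NA,NA,NA,-0.39,2,4857,4663
Pre-Mission Training,Pre-Mission Training,13,3904,3589,4219,1798,390,1715,2.17,NA,NA,NA,NA,0.24,1,4225,4092
Weapons Training,Weapons Training,12,3682,3076,4289,1868,368,1447,1.97,3935,3543,4327,253,-0.19,0,3734,3574
Urban Combat,Urban Combat,9,5215,4665,5766,1712,522,2982,3.05,2503,2083,2924,-2712,-3.30,3,5528,5276
Squad Raids,Squad Raids,12,4801,4426,5175,1838,480,2483,2.62,3118,2619,3616,-1683,-3.25,2,4767,4921
Platoon Raids,Platoon Raids,11,4484,3788,5180,1912,448,2554,2.31,4529,4126,4931,45,-1.96,1,4118,4381
Small Unit Ranger Training (classroom),Small Unit Ranger Training,6,3719,3452,3985,1800,372,1546,2.06,3134,2838,3430,-584,NA,0,3352,3381
Small Unit Ranger Training (field training),Small Unit Ranger Training,7,4924,4513,5335,1800,493,2631,2.73,2850,2497,3203,-2074,NA,2,4765,4814
Ranger Selection Assessment Program,Ranger Selection Assessment Program,17,4264,4089,4440,1733,426,2105,2.47,2957,2814,3101,-1307,-1.24,2,4610,4621
Raider Spirit,Raider Spirit,13,6317,5886,6748,1894,632,3791,3.34,2385,2183,2588,-3932,-4.47,3,5680,5799
Close Quarters Battle,Close Quarters Battle,9,4189,3824,4555,1915,419,1856,2.19,2816,2440,3191,-1374,-0.40,1,4457,4426
Derna Bridge,Derna Bridge,13,3736,3546,3926,1936,374,1427,1.93,2701,2256,3146,-1035,-1.48,0,3719,3769
Overall,Overall,133,4468,4311,4624,1827,447,2219,2.45,3086,2941,3231,-1433,-1.75,NA,4463,4462
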