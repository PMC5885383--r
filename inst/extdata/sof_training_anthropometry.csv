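course,n,bm_mean,bm_ci_low,bm_ci_high,ffm_mean,ffm_ci_low,ffm_ci_high,fm_mean,fm_ci_low,fm_ci_high
Combat Dive School,11,81.6,76.9,86.2,63.8,60.2,67.3,17.8,15.2,20.4
Pre-Mission Training,13,83.1,79.6,86.6,66.1,63.3,68.9,17.0,14.0,20.0
Weapons Training,12,87.6,82.8,92.4,69.3,64.1,74.5,18.3,14.5,22.1
Urban Combat,9,80.8,75.3,86.4,62.1,57.7,66.5,18.7,15.5,22.0
Squad Raids,12,79.67,75.3,84.0,67.9,63.0,72.8,11.8,9.0,14.6
Platoon Raids,11,82.2,74.0,90.4,71.3,63.0,79.7,9.3,5.4,13.3
Small Unit Ranger Training,13,79.6,75.0,84.3,66.2,63.0,69.4,13.4,10.7,16.2
Ranger Selection Assessment Program,17,76.4,71.8,81.0,63.1,59.1,67.0,13.3,11.9,14.8
Raider Spirit,13,84.0,80.2,87.8,70.5,67.9,73.1,13.5,11.7,15.3
Close Quarters Battle,9,87.9,79.6,96.2,71.5,63.9,79.0,16.5,14.6,18.4
Derna Bridge,13,87.3,83.5,91.0,72.4,69.4,75.5,14.8,12.0,17.6
Overall,133,82.2,80.8,83.6,67.4,66.2,68.6,14.8,14.0,15.6
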