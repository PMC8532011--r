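source,subgroup,quantity,numerator,denominator,printed_pct,target_id
abstract,asthma,fulfilling_pct,3194,14644,21.81,t1
abstract,asthma,in_system_fulfilling_6m,797,1194,66.75,t2
abstract,asthma,in_system_fulfilling_12m,1997,2975,67.13,t3
table2,asthma,fulfilling_pct,3194,14640,21.81,
table2,asthma,in_system_all_6m,2648,7135,37.11,
table2,asthma,in_system_fulfilling_6m,797,1194,66.75,
table2,asthma,in_system_all_12m,6857,18206,37.66,
table2,asthma,in_system_fulfilling_12m,1997,2975,67.13,
table2,ckd,fulfilling_pct,5081,25363,20.03,
table2,ckd,in_system_all_6m,7503,18404,40.77,
table2,ckd,in_system_fulfilling_6m,2178,2918,74.64,t4
table2,ckd,in_system_all_12m,19558,45994,42.52,
table2,ckd,in_system_fulfilling_12m,5634,7496,75.16,
table2,copd,fulfilling_pct,1456,7579,19.21,
table2,copd,in_system_all_6m,2587,6659,38.85,
table2,copd,in_system_fulfilling_6m,831,1157,71.82,
table2,copd,in_system_all_12m,7026,16941,41.47,
table2,copd,in_system_fulfilling_12m,2179,3009,72.42,
table2,t1d,fulfilling_pct,361,2879,12.54,
table2,t1d,in_system_all_6m,317,1333,23.78,
table2,t1d,in_system_fulfilling_6m,63,112,56.25,t5
table2,t1d,in_system_all_12m,845,3330,25.38,
table2,t1d,in_system_fulfilling_12m,169,281,60.14,
table2,t2d,fulfilling_pct,7744,56551,13.69,
table2,t2d,in_system_all_6m,10926,30707,35.58,
table2,t2d,in_system_fulfilling_6m,2847,3923,72.57,
table2,t2d,in_system_all_12m,29272,79775,36.69,
table2,t2d,in_system_fulfilling_12m,7177,10065,71.31,
prior_study,all_adults,fulfilling_pct,55707,348054,16.01,t6
prior_study,all_adults,in_system_all_6m,39171,123162,31.80,t7
prior_study,all_adults,in_system_fulfilling_6m,10501,15135,69.38,t8
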