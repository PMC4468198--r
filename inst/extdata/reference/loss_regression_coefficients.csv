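transect,species,beta0,se_beta0,beta1,se_beta1,df,f_stat,t_stat,p_value,r2
Kilimanjaro,C. partellus,-20.893,8.051,3.087,0.753,1,16.798,4.099,0.055,0.894
Taita,C. partellus,-27.961,10.998,3.844,1.059,1,13.155,3.627,0.068,0.868
Kilimanjaro,B. fusca,-39.554,16.468,6.855,2.370,1,8.364,2.892,0.102,0.807
Taita,B. fusca,-71.386,27.876,12.272,4.311,1,8.104,2.847,0.104,0.802
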