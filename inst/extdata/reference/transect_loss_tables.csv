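transect,species,zone,observed_pct,current_pct,future_pct
Kilimanjaro,C. partellus,highland tropics,0.01,2.84,8.34
Kilimanjaro,C. partellus,moist transitional,11.1,6.86,12.41
Kilimanjaro,C. partellus,dry mid altitude,11.09,12.14,17.85
Kilimanjaro,C. partellus,lowland tropical,22.69,23.06,28.10
Taita,C. partellus,highland tropics,0.01,1.74,7.74
Taita,C. partellus,moist transitional,11.1,7.04,13.26
Taita,C. partellus,dry mid altitude,11.09,14.66,21.19
Taita,C. partellus,lowland tropical,22.69,21.42,28.11
Kilimanjaro,B. fusca,highland tropics,10.70,13.51,14.88
Kilimanjaro,B. fusca,moist transitional,14.60,10.97,15.77
Kilimanjaro,B. fusca,dry mid altitude,5.54,5.69,12.27
Kilimanjaro,B. fusca,lowland tropical,0.48,1.17,9.46
Taita,B. fusca,highland tropics,10.70,13.40,36.85
Taita,B. fusca,moist transitional,14.60,10.77,31.67
Taita,B. fusca,dry mid altitude,5.54,6.91,20.65
Taita,B. fusca,lowland tropical,0.48,0.53,13.78
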