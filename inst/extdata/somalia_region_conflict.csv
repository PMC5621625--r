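region,battle,remote_violence,violence_against_civilians,other
Bari,16,7,21,3
Mudug,14,3,21,3
Nugaal,6,2,8,1
Awdal,2,0,5,0
Sanaag,4,0,6,0
Sool,8,0,11,8
Togdheer,9,0,8,1
Woqooyi Galbeed,5,0,19,3
Bakool,7,1,4,8
Banadir,366,74,123,31
Bay,31,0,29,14
Galgaduud,36,2,11,6
Gedo,11,0,7,13
Hiraan,48,3,33,10
Juba Dhexe,9,0,4,1
Juba Hoose,26,1,20,13
Shabelle Dhexe,22,0,16,11
Shabelle Hoose,140,16,47,7
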