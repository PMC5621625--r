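zone,region,clusters,children,stunted,wasted
North East,Bari,9,756,201,174
North East,Mudug,61,6188,804,1055
North East,Nugaal,24,1673,383,322
North West,Awdal,26,862,7,177
North West,Sanaag,14,412,3,97
North West,Sool,3,142,18,24
North West,Togdheer,12,673,362,124
North West,Woqooyi Galbeed,23,2465,1378,480
South-Central,Bakool,75,3534,1150,1330
South-Central,Banadir,1,51,0,11
South-Central,Bay,98,5568,2133,1798
South-Central,Galgaduud,77,5831,1908,879
South-Central,Gedo,111,6985,1999,2616
South-Central,Hiraan,142,10743,2260,2085
South-Central,Juba Dhexe,77,5253,2734,960
South-Central,Juba Hoose,71,5560,1553,926
South-Central,Shabelle Dhexe,101,7650,2414,1322
South-Central,Shabelle Hoose,141,9432,3432,1355
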