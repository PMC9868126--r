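"animal","group","R001","R002","R003","R004","R005","R006","R007","R008","R009","R010","R011","R012","R013","R014","R015","R016","R017","R018","R019","R020"
"water_1","water",1904,14,221,2422,4,1,6,54,14,88,59,548,45,24,0,714,4,0,169,125
"water_2","water",743,2,197,1268,8,5,23,9,30,158,407,1695,370,7,1,745,0,0,124,15
"water_3","water",3447,8,282,1469,6,22,22,153,84,1242,23,314,26,10,0,919,23,0,1033,196
"water_4","water",2419,7,195,2781,8,26,63,17,130,982,13,263,10,5,1,1921,7,1,196,22
"water_5","water",3962,24,337,2657,1,3,3,7,62,1339,14,110,39,5,0,340,11,2,560,172
"water_6","water",2166,15,139,1733,11,52,163,13,16,78,127,664,110,46,1,902,12,1,206,42
"water_7","water",1859,9,174,1255,2,56,29,19,9,396,118,375,100,20,1,1393,13,0,268,14
"sugar1d_1","sugar1d",1060,6,122,1539,3,188,158,61,37,139,31,415,39,27,0,2749,3,0,69,49
"sugar1d_2","sugar1d",137,2,30,524,2,19,54,169,53,457,23,165,5,9,0,932,2,0,140,55
"sugar1d_3","sugar1d",2665,13,552,3049,12,63,240,79,7,145,23,164,17,102,0,1149,21,5,1140,27
"sugar1d_4","sugar1d",1375,2,38,271,3,117,163,76,134,227,30,253,48,27,5,1946,6,0,242,87
"sugar1d_5","sugar1d",577,8,128,2241,7,123,30,342,378,1707,134,817,139,10,1,601,5,1,142,22
"sugar7d_1","sugar7d",2090,15,292,1427,15,33,47,35,4,131,191,725,121,24,1,6180,25,2,468,209
"sugar7d_2","sugar7d",1270,14,131,3053,1,33,54,81,25,522,31,292,50,64,2,4858,0,0,15,12
"sugar7d_3","sugar7d",3156,13,94,830,1,0,2,92,59,224,30,101,30,7,0,372,2,0,51,19
"sugar7d_4","sugar7d",1549,8,77,737,8,41,108,36,35,552,19,86,105,3,1,543,1,0,36,46
"sugar7d_5","sugar7d",1077,13,52,701,10,82,45,10,23,358,21,56,40,24,2,2094,10,0,130,28
"sugar7d_6","sugar7d",425,15,80,2071,3,13,31,30,15,205,301,932,289,16,0,5247,29,3,765,76
"sugar7d_7","sugar7d",18534,19,739,7430,0,4,12,9,5,48,26,290,15,18,0,1081,2,1,96,87
"saline_1","saline",4052,44,121,2525,1,12,16,24,55,345,59,834,143,54,0,1945,2,0,79,47
"saline_2","saline",2228,41,462,3021,4,19,11,30,5,322,215,285,84,12,0,1888,43,3,805,541
"saline_3","saline",2173,9,168,889,0,8,13,39,172,1296,196,1286,74,30,0,1775,1,2,286,120
"saline_4","saline",2306,35,157,876,7,19,18,12,25,104,77,254,48,28,0,661,3,0,76,2
"saline_5","saline",3578,7,51,5334,7,33,62,89,22,527,26,167,66,38,0,472,7,2,92,19
"saline_6","saline",871,15,98,1201,1,124,168,49,43,156,112,763,275,7,0,1345,11,0,175,70
"saline_7","saline",3964,108,2003,6607,3,20,134,84,23,660,27,377,16,12,0,296,5,1,286,137
"cocaine1d_1","cocaine1d",3187,97,145,5995,7,41,126,88,47,120,124,701,73,41,2,867,27,2,309,63
"cocaine1d_2","cocaine1d",2659,33,208,3492,2,25,31,62,27,253,266,3289,113,62,4,1827,56,2,1326,209
"cocaine1d_3","cocaine1d",1329,124,499,12986,2,5,4,15,26,292,15,196,28,20,0,1806,18,0,280,19
"cocaine1d_4","cocaine1d",2695,57,208,1035,11,54,45,107,62,364,610,992,215,29,2,2925,15,0,467,69
"cocaine1d_5","cocaine1d",5675,35,708,6683,4,59,123,103,62,1687,46,251,63,85,2,3875,6,0,55,40
"cocaine1d_6","cocaine1d",831,6,68,1275,0,19,5,25,28,83,16,251,91,72,0,3512,13,0,245,93
"cocaine7d_1","cocaine7d",5932,87,2563,9206,1,31,7,62,10,357,89,1645,182,3,1,192,11,0,178,18
"cocaine7d_2","cocaine7d",11875,14,253,4104,16,10,22,35,51,648,62,160,54,50,2,1551,23,1,45,126
"cocaine7d_3","cocaine7d",12739,24,699,5432,20,13,38,4,3,188,63,216,62,25,2,532,8,1,624,136
"cocaine7d_4","cocaine7d",11227,118,283,3547,3,24,10,109,87,977,115,397,53,61,3,1542,46,1,934,80
"cocaine7d_5","cocaine7d",3114,55,599,4453,13,27,24,94,21,324,48,475,15,89,1,2390,40,2,596,107
"cocaine7d_6","cocaine7d",4404,33,76,6642,15,29,11,25,18,22,71,122,82,15,4,3123,11,0,85,29
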