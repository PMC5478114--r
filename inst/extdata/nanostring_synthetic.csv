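gene,is_control,FFPE01,FFPE02,FFPE03,FFPE04,FFPE05,FFPE06,FFPE07,FFPE08
Aurkb,FALSE,1933,3407,886,1032,531,3572,537,1595
Ccna2,FALSE,2220,2011,896,1455,670,1818,1164,2136
Chaf1b,FALSE,1439,2667,1083,1116,1374,1591,393,1212
Ccnb1,FALSE,722,1093,554,703,310,830,429,1186
Scrn1,FALSE,604,283,121,162,115,324,220,535
C1qb,FALSE,3491,3179,1771,2924,1038,3387,978,4357
CD74,FALSE,424,405,124,178,146,272,168,254
Ccr2,FALSE,755,921,461,828,471,1110,619,1528
Itgb2,FALSE,536,693,181,305,174,471,176,487
Vcam1,FALSE,197,278,64,64,71,124,44,181
CD180,FALSE,3003,2535,903,828,635,1978,925,1670
CD72,FALSE,760,521,178,153,155,274,127,483
Npy,FALSE,10300,10412,3545,5860,3651,6022,3503,7436
Cldn8,FALSE,1589,934,443,477,583,912,588,1386
Nrp1,FALSE,902,1823,565,815,269,860,651,1019
Atp7b,FALSE,1543,3601,1168,1241,825,2119,675,1799
St8sia4,FALSE,1638,1882,1399,2079,981,1556,1293,4660
Spink5,FALSE,388,669,143,219,148,234,181,615
Ctss,FALSE,3373,3858,813,1986,945,1266,1125,4225
Aim2,FALSE,5817,1458,1623,1572,1113,3278,1622,2422
CD48,FALSE,2907,2726,962,477,675,1665,678,1572
C4ORF8,TRUE,5460,5064,1743,1858,1020,3064,851,2881
CAPZB,TRUE,3530,2081,2495,1903,716,4755,1127,3097
EIF3A,TRUE,764,1941,580,864,744,987,755,1139
RTN3,TRUE,373,436,214,218,182,429,251,478
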