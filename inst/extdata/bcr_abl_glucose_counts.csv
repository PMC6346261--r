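source,drug,stratum,n_event_drug,n_drug,n_event_nodrug,n_nodrug,printed_ror,printed_ci_low,printed_ci_high
FAERS,imatinib,overall,572,8771,176388,2167224,0.79,0.722,0.857
FAERS,dasatinib,overall,306,4637,176654,2171358,0.80,0.708,0.896
FAERS,nilotinib,overall,514,5122,176446,2170873,1.26,1.149,1.382
FAERS,bosutinib,overall,42,781,176918,2175214,0.64,0.459,0.876
FAERS,ponatinib,overall,114,1284,176846,2174711,1.10,0.900,1.335
JADER,imatinib,overall,75,3429,20064,378563,0.40,0.313,0.503
JADER,dasatinib,overall,23,1019,20116,380973,0.41,0.261,0.625
JADER,nilotinib,overall,93,1358,20046,380634,1.32,1.059,1.634
JADER,bosutinib,overall,3,124,20136,381868,0.45,0.091,1.333
FAERS,imatinib,male,266,4850,67905,815539,0.64,0.562,0.723
FAERS,dasatinib,male,148,2362,68023,818027,0.74,0.620,0.871
FAERS,nilotinib,male,289,2876,67882,817513,1.23,1.088,1.394
FAERS,bosutinib,male,20,373,68151,820016,0.63,0.377,0.980
FAERS,ponatinib,male,56,662,68115,819727,1.02,0.761,1.342
FAERS,imatinib,female,306,3921,108483,1351685,0.97,0.860,1.091
FAERS,dasatinib,female,158,2275,108631,1353331,0.86,0.723,1.006
FAERS,nilotinib,female,225,2246,108564,1353360,1.28,1.107,1.466
FAERS,bosutinib,female,22,408,108767,1355198,0.65,0.405,1.003
FAERS,ponatinib,female,58,622,108731,1354984,1.18,0.883,1.546
JADER,imatinib,male,35,1926,10395,192651,0.32,0.225,0.453
JADER,dasatinib,male,12,576,10418,194001,0.37,0.193,0.660
JADER,nilotinib,male,60,835,10370,193742,1.37,1.034,1.783
JADER,bosutinib,male,3,78,10427,194499,0.71,0.142,2.145
JADER,imatinib,female,40,1503,9669,185912,0.50,0.354,0.682
JADER,dasatinib,female,11,443,9698,186972,0.47,0.231,0.842
JADER,nilotinib,female,33,523,9676,186892,1.23,0.839,1.757
JADER,bosutinib,female,0,41,7162,157401,NA,NA,NA
FAERS,imatinib,20-60s,393,6392,132131,1641998,0.75,0.674,0.829
FAERS,dasatinib,20-60s,220,3383,132304,1645007,0.80,0.690,0.912
FAERS,nilotinib,20-60s,325,3534,132199,1644856,1.16,1.031,1.299
FAERS,bosutinib,20-60s,27,542,132497,1647848,0.60,0.391,0.883
FAERS,ponatinib,20-60s,80,973,132444,1647417,1.02,0.805,1.289
FAERS,imatinib,70-90s,179,2379,44257,525227,0.88,0.755,1.031
FAERS,dasatinib,70-90s,86,1254,44350,526352,0.80,0.635,0.997
FAERS,nilotinib,70-90s,189,1588,44247,526018,1.47,1.257,1.714
FAERS,bosutinib,70-90s,15,239,44421,527367,0.73,0.401,1.227
FAERS,ponatinib,70-90s,34,311,44402,527295,1.33,0.906,1.911
JADER,imatinib,20-60s,40,2088,10542,223081,0.39,0.280,0.538
JADER,dasatinib,20-60s,17,678,10565,224491,0.52,0.301,0.841
JADER,nilotinib,20-60s,55,794,10527,224375,1.51,1.127,1.991
JADER,bosutinib,20-60s,1,73,10581,225096,0.28,0.007,1.620
JADER,imatinib,70-90s,35,1341,9522,155482,0.41,0.285,0.575
JADER,dasatinib,70-90s,6,341,9551,156482,0.28,0.100,0.606
JADER,nilotinib,70-90s,38,564,9519,156259,1.11,0.779,1.550
JADER,bosutinib,70-90s,2,51,9555,156772,0.63,0.074,2.397
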