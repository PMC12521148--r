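strategy,state,category,mean,sd
A1,hospitalization,ics,132.26,0.00
A1,hospitalization,tcm,20.72,58.60
A1,hospitalization,other,1836.62,990.70
A1,hospitalization,non_medication,8135.29,2839.74
A2,hospitalization,ics,197.40,136.91
A2,hospitalization,tcm,15.97,51.02
A2,hospitalization,other,1766.34,1973.44
A2,hospitalization,non_medication,10184.09,11012.27
A,hospitalization,ics,180.03,120.13
A,hospitalization,tcm,17.24,52.14
A,hospitalization,other,1785.08,1748.73
A,hospitalization,non_medication,9637.74,9519.03
B1,hospitalization,ics,145.31,11.58
B1,hospitalization,tcm,17.23,39.81
B1,hospitalization,other,1584.29,904.82
B1,hospitalization,non_medication,6892.96,2128.60
B2,hospitalization,ics,143.68,12.21
B2,hospitalization,tcm,21.32,39.75
B2,hospitalization,other,1674.82,931.19
B2,hospitalization,non_medication,6816.33,3033.16
B,hospitalization,ics,144.86,11.56
B,hospitalization,tcm,18.36,39.12
B,hospitalization,other,1609.27,896.25
B,hospitalization,non_medication,6871.82,2353.21
A1,outpatient_exacerbation,ics,44.09,68.30
A1,outpatient_exacerbation,tcm,84.59,142.01
A1,outpatient_exacerbation,other,114.01,156.17
A1,outpatient_exacerbation,non_medication,521.27,642.63
A2,outpatient_exacerbation,ics,141.00,213.28
A2,outpatient_exacerbation,tcm,85.83,132.06
A2,outpatient_exacerbation,other,346.87,326.61
A2,outpatient_exacerbation,non_medication,1117.77,1107.85
A,outpatient_exacerbation,ics,106.80,179.35
A,outpatient_exacerbation,tcm,85.39,131.16
A,outpatient_exacerbation,other,264.68,295.72
A,outpatient_exacerbation,non_medication,907.24,991.20
B1,outpatient_exacerbation,ics,159.81,125.69
B1,outpatient_exacerbation,tcm,94.41,147.26
B1,outpatient_exacerbation,other,373.57,293.07
B1,outpatient_exacerbation,non_medication,667.30,536.32
B2,outpatient_exacerbation,ics,327.08,285.20
B2,outpatient_exacerbation,tcm,18.66,40.08
B2,outpatient_exacerbation,other,657.03,964.31
B2,outpatient_exacerbation,non_medication,1406.77,1751.37
B,outpatient_exacerbation,ics,215.56,203.83
B,outpatient_exacerbation,tcm,69.16,126.34
B,outpatient_exacerbation,other,468.06,598.05
B,outpatient_exacerbation,non_medication,913.79,1117.10
A1,symptom_free,ics,247.99,148.92
A1,symptom_free,tcm,87.70,100.91
A1,symptom_free,other,1316.71,2833.15
A1,symptom_free,non_medication,931.50,862.73
A2,symptom_free,ics,502.23,702.08
A2,symptom_free,tcm,188.41,437.03
A2,symptom_free,other,433.53,602.72
A2,symptom_free,non_medication,1143.78,1181.99
A,symptom_free,ics,432.09,609.10
A,symptom_free,tcm,160.63,375.59
A,symptom_free,other,677.17,1558.06
A,symptom_free,non_medication,1085.22,1092.39
B1,symptom_free,ics,857.25,1337.13
B1,symptom_free,tcm,422.80,483.44
B1,symptom_free,other,1786.33,3237.53
B1,symptom_free,non_medication,2500.68,2107.01
B2,symptom_free,ics,1881.11,1188.74
B2,symptom_free,tcm,614.13,466.06
B2,symptom_free,other,3428.26,3982.17
B2,symptom_free,non_medication,4332.94,1583.35
B,symptom_free,ics,1139.70,1359.14
B,symptom_free,tcm,475.58,478.35
B,symptom_free,other,2239.27,3465.41
B,symptom_free,non_medication,3006.13,2119.53
A1,hospitalization,medication,1989.60,977.39
A2,hospitalization,medication,1979.70,2115.36
A,hospitalization,medication,1982.34,1863.04
B1,hospitalization,medication,1746.83,892.26
B2,hospitalization,medication,1839.83,910.64
B,hospitalization,medication,1772.49,881.91
A1,outpatient_exacerbation,medication,242.69,142.37
A2,outpatient_exacerbation,medication,573.70,543.66
A,outpatient_exacerbation,medication,456.87,466.53
B1,outpatient_exacerbation,medication,627.79,424.47
B2,outpatient_exacerbation,medication,1002.77,1263.44
B,outpatient_exacerbation,medication,752.78,797.45
A1,symptom_free,medication,1652.40,2924.12
A2,symptom_free,medication,1124.17,1546.75
A,symptom_free,medication,1269.89,1975.91
B1,symptom_free,medication,3066.38,4076.71
B2,symptom_free,medication,5923.50,5123.06
B,symptom_free,medication,3854.55,4220.19
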