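strategy,state,cost_cny,probability,utility_qaly
A1,hospitalization,1989.60,0.1739,11.6460
A1,outpatient_exacerbation,242.69,0.1739,13.8060
A1,symptom_free,1652.40,0.6522,15.6060
A2,hospitalization,1979.70,0.1474,11.6460
A2,outpatient_exacerbation,573.70,0.1789,13.8060
A2,symptom_free,1124.17,0.6737,15.6060
A,hospitalization,1982.34,0.1525,11.6460
A,outpatient_exacerbation,456.87,0.1780,13.8060
A,symptom_free,1269.89,0.6695,15.6060
B1,hospitalization,1746.83,0.0640,11.6460
B1,outpatient_exacerbation,627.79,0.1366,13.8060
B1,symptom_free,3066.38,0.7994,15.6060
B2,hospitalization,1839.83,0.0394,11.6460
B2,outpatient_exacerbation,1002.77,0.1232,13.8060
B2,symptom_free,5923.50,0.8374,15.6060
B,hospitalization,1772.49,0.0548,11.6460
B,outpatient_exacerbation,752.78,0.1316,13.8060
B,symptom_free,3854.55,0.8135,15.6060
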