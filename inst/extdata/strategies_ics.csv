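strategy,state,cost_cny,probability,utility_qaly
A1,hospitalization,132.26,0.1739,11.6460
A1,outpatient_exacerbation,44.09,0.1739,13.8060
A1,symptom_free,247.99,0.6522,15.6060
A2,hospitalization,197.40,0.1474,11.6460
A2,outpatient_exacerbation,141.00,0.1789,13.8060
A2,symptom_free,502.23,0.6737,15.6060
A,hospitalization,180.03,0.1525,11.6460
A,outpatient_exacerbation,106.80,0.1780,13.8060
A,symptom_free,432.09,0.6695,15.6060
B1,hospitalization,145.31,0.0640,11.6460
B1,outpatient_exacerbation,159.81,0.1366,13.8060
B1,symptom_free,857.25,0.7994,15.6060
B2,hospitalization,143.68,0.0394,11.6460
B2,outpatient_exacerbation,327.08,0.1232,13.8060
B2,symptom_free,1881.11,0.8374,15.6060
B,hospitalization,144.86,0.0548,11.6460
B,outpatient_exacerbation,215.56,0.1316,13.8060
B,symptom_free,1139.70,0.8135,15.6060
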