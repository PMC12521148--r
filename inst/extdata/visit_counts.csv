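strategy,state,visits
A1,hospitalization,8
A1,outpatient_exacerbation,8
A1,symptom_free,30
A2,hospitalization,28
A2,outpatient_exacerbation,34
A2,symptom_free,128
A,hospitalization,36
A,outpatient_exacerbation,42
A,symptom_free,158
B1,hospitalization,22
B1,outpatient_exacerbation,47
B1,symptom_free,275
B2,hospitalization,8
B2,outpatient_exacerbation,25
B2,symptom_free,170
B,hospitalization,30
B,outpatient_exacerbation,72
B,symptom_free,445
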