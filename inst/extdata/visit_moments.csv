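strategy,n_patients,visit_mean,visit_sd,followup_mean,followup_sd
A1,8,5.8,3.8,16.3,16.1
A2,22,8.6,9.2,20.5,26.7
A,30,7.8,8.2,19.4,24.1
B1,21,16.4,15.5,35.4,24.9
B2,8,25.6,13.1,50.3,17.81
B,29,18.9,15.2,39.5,23.8
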