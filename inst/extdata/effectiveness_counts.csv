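strategy,n_patients,threshold_months,n_achieving
A1,8,3,6
A1,8,6,5
A1,8,12,3
A1,8,24,1
A2,22,3,11
A2,22,6,8
A2,22,12,8
A2,22,24,3
A,30,3,17
A,30,6,13
A,30,12,11
A,30,24,4
B1,21,3,18
B1,21,6,16
B1,21,12,14
B1,21,24,6
B2,8,3,8
B2,8,6,7
B2,8,12,6
B2,8,24,5
B,29,3,26
B,29,6,23
B,29,12,20
B,29,24,11
Total,59,3,43
Total,59,6,36
Total,59,12,31
Total,59,24,15
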