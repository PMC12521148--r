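strategy,cost_basis,mean_cost
A1,medication,3824.02
A2,medication,3339.63
A,medication,3468.80
B1,medication,5291.53
B2,medication,8766.09
B,medication,6250.03
A1,ics,413.31
A2,ics,747.30
A,ics,658.24
B1,ics,1124.32
B2,ics,2351.86
B,ics,1462.96
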