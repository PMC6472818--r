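tech_id,scope,assur_rank,perf_rank
A,SP,4,3
B,SP,5,5
C,SP,1,1
D,SP,6,6
E,SP,3,2
F,SP,2,4
A,BL,3,1
B,BL,4,6
C,BL,2,4
D,BL,6,5
E,BL,5,3
F,BL,1,2
A,ST,3,1
B,ST,2,6
C,ST,4,4
D,ST,5,5
E,ST,6,3
F,ST,1,2
A,overall,2,1
B,overall,3,6
C,overall,3,4
D,overall,6,5
E,overall,3,3
F,overall,1,2
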