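message_id,self_report_total,self_report_total_rank,lab_total,lab_total_rank
H1,10,1,18,12
H2,17,5,14,1
HS1,15,4,25,10
HS2,10,1,15,6
HF1,24,7,22,8
HF2,13,3,12,3
A1,21,6,20,4
A2,33,8,21,9
AS1,39,9,28,5
AS2,44,12,20,7
AF1,42,11,7,2
AF2,39,9,31,11
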