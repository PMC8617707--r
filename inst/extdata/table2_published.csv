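message_id,equal_attributes_score,equal_attributes_rank,equal_attributes_tie,equal_studies_score,equal_studies_rank,equal_studies_tie,prefer_self_report_score,prefer_self_report_rank,prefer_self_report_tie,prefer_lab_score,prefer_lab_rank,prefer_lab_tie
H1,4.0,3,FALSE,6.5,5,TRUE,4.4,4,FALSE,4.75,4,TRUE
H2,4.4,4,FALSE,3.0,1,TRUE,3.6,3,FALSE,4.75,4,TRUE
HS1,5.7,5,FALSE,7.0,7,TRUE,5.0,5,TRUE,7.25,7,TRUE
HS2,3.6,1,TRUE,3.5,3,FALSE,3.2,1,TRUE,4.00,2,FALSE
HF1,6.6,7,FALSE,7.5,9,FALSE,6.4,7,FALSE,7.25,7,TRUE
HF2,3.6,1,TRUE,3.0,1,TRUE,3.2,1,TRUE,3.75,1,FALSE
A1,5.9,6,FALSE,5.0,4,FALSE,5.0,5,TRUE,6.50,6,FALSE
A2,7.7,9,FALSE,8.5,10,FALSE,8.4,8,FALSE,7.25,7,TRUE
AS1,9.6,11,FALSE,7.0,7,TRUE,8.8,9,TRUE,9.25,11,FALSE
AS2,9.1,10,FALSE,9.5,11,FALSE,10.2,12,FALSE,8.00,10,FALSE
AF1,7.0,8,FALSE,6.5,5,TRUE,8.8,9,TRUE,4.50,3,FALSE
AF2,10.0,12,FALSE,10.0,12,FALSE,10.0,11,FALSE,10.00,12,FALSE
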