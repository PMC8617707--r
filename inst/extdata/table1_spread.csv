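message_id,receptivity,engagement,positive_attitude,negative_emotion,hr_deceleration,recognition_accuracy,visual_attention
H1,0.16,0.14,0.18,0.11,0.50,0.03,730.11
H2,0.19,0.16,0.20,0.12,0.57,0.03,779.43
HS1,0.19,0.16,0.20,0.12,0.57,0.03,786.94
HS2,0.17,0.15,0.19,0.11,0.47,0.02,763.33
HF1,0.18,0.15,0.19,0.12,0.51,0.03,765.70
HF2,0.19,0.16,0.20,0.12,0.52,0.03,796.33
A1,0.17,0.14,0.18,0.11,0.51,0.03,781.80
A2,0.16,0.14,0.18,0.11,0.47,0.03,781.45
AS1,0.18,0.16,0.20,0.12,0.45,0.04,764.58
AS2,0.17,0.14,0.18,0.11,0.51,0.03,745.07
AF1,0.17,0.15,0.19,0.12,0.52,0.03,806.43
AF2,0.18,0.15,0.20,0.12,0.43,0.03,752.70
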