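patient_id,accuracy_pct,f1
P1,74.00,0.7436
P2,67.22,0.6308
P3,68.30,0.5803
P4,67.95,0.5882
P5,71.42,0.6224
P6,68.99,0.5800
P7,65.91,0.5452
P8,69.55,0.5843
P9,70.14,0.6160
P10,70.00,0.6130
P11,73.70,0.7373
P12,74.73,0.7262
P13,74.74,0.7485
P14,67.95,0.5863
P15,67.67,0.5512
P16,75.27,0.7162
P17,74.91,0.7230
P18,69.51,0.6033
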