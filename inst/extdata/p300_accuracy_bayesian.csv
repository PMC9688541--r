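patient_id,accuracy_pct,f1
P1,75.55,0.7803
P2,67.56,0.6035
P3,62.88,0.5327
P4,62.08,0.5966
P5,68.06,0.6259
P6,62.81,0.6099
P7,63.47,0.6046
P8,64.00,0.5968
P9,68.96,0.6663
P10,67.43,0.6234
P11,75.28,0.7252
P12,77.00,0.7702
P13,74.34,0.7403
P14,66.53,0.6269
P15,64.90,0.5692
P16,68.23,0.6966
P17,75.82,0.7443
P18,66.49,0.6842
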