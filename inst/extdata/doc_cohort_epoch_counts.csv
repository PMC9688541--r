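patient_id,n_total,n_p300,n_non_p300
P1,1100,550,550
P2,900,450,450
P3,2880,1395,1485
P4,2880,1398,1482
P5,2880,1376,1504
P6,2880,1387,1493
P7,2880,1378,1502
P8,3400,1647,1753
P9,2880,1388,1492
P10,2880,1389,1491
P11,1080,540,540
P12,1100,550,550
P13,760,380,380
P14,1100,550,550
P15,2880,1379,1501
P16,3000,1454,1546
P17,2880,1386,1494
P18,2880,1389,1491
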