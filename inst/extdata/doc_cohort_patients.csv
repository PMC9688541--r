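patient_id,age,gender,etiology,time_since_injury_months,diagnosis_before,diagnosis_after,crsr_before_total,crsr_before_auditory,crsr_before_visual,crsr_before_motor,crsr_before_oromotor,crsr_before_communication,crsr_before_arousal,crsr_after_total,crsr_after_auditory,crsr_after_visual,crsr_after_motor,crsr_after_oromotor,crsr_after_communication,crsr_after_arousal
P1,43,M,TBI,5,UWS,MCS+,5,1,0,1,1,0,2,9,3,1,2,1,0,2
P2,51,M,TBI,20,UWS,UWS,9,2,1,2,2,0,2,9,2,1,2,2,0,2
P3,29,M,ABI,8.5,UWS,UWS,4,1,0,1,0,0,2,4,1,0,1,0,0,2
P4,37,M,ABI,2,UWS,UWS,5,0,0,2,1,0,2,5,0,0,2,1,0,2
P5,38,M,TBI,1,UWS,UWS,7,1,1,2,1,0,2,7,1,1,2,1,0,2
P6,33,M,TBI,2,UWS,UWS,7,1,0,2,2,0,2,7,1,0,2,2,0,2
P7,40,M,ABI,2,UWS,UWS,5,1,0,2,0,0,2,7,1,0,2,2,0,2
P8,52,M,CVD,4.5,UWS,MCS-,5,1,1,0,1,0,2,9,2,3,0,2,0,2
P9,42,M,CVD,4,UWS,MCS+,7,1,1,2,1,0,2,11,3,2,3,1,0,2
P10,26,M,CVD,1,UWS,MCS+,7,1,1,2,1,0,2,15,4,5,2,1,1,2
P11,48,M,TBI,3.5,MCS-,MCS+,11,1,2,5,1,0,2,16,3,3,5,2,1,2
P12,34,M,TBI,1.5,MCS-,MCS+,9,1,1,5,1,0,1,15,4,4,5,1,0,1
P13,37,M,TBI,4,MCS-,MCS+,9,1,3,2,1,0,2,19,3,5,6,2,1,2
P14,20,M,TBI,4,MCS-,MCS-,7,1,0,3,1,0,2,7,1,0,3,1,0,2
P15,19,M,ABI,1.5,MCS-,MCS-,8,1,1,3,1,0,2,8,1,1,3,1,0,2
P16,17,M,TBI,2,MCS-,MCS+,8,1,1,3,1,0,2,18,4,5,3,1,2,3
P17,46,F,TBI,1.5,MCS-,MCS+,7,1,0,3,1,0,2,19,3,5,6,2,1,2
P18,46,M,CVD,2,MCS-,MCS+,9,1,1,4,1,0,2,20,4,5,6,2,1,2
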