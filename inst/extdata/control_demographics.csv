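patient_id,age,gender,years_diagnosed,medication,dominant_hand,group
1,64,Male,NA,None,Right,control
2,70,Female,NA,None,Right,control
3,62,Male,NA,None,Right,control
4,65,Female,NA,None,Right,control
5,67,Male,NA,None,Right,control
6,68,Female,NA,None,Right,control
7,72,Male,NA,None,Right,control
8,63,Female,NA,None,Right,control
9,69,Male,NA,None,Right,control
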