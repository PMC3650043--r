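patient_id,score,time,event
1,0.9,1,1
2,0.2,3.2,0
3,0.5,2.1,1
4,0.5,4,1
5,0.1,2.1,0
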