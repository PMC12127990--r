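"participant_id","trial_index","phase","cs_type","rewarded"
"P1",1,1,"csplus",1
"P1",2,1,"csminus",0
"P1",3,2,"csplus",1
"P1",4,2,"csminus",0
"P2",1,1,"csplus",1
"P2",2,1,"csminus",0
"P2",3,2,"csplus",1
"P2",4,2,"csminus",0
"P3",1,1,"csplus",1
"P3",2,1,"csminus",0
"P3",3,2,"csplus",1
"P3",4,2,"csminus",0
"P4",1,1,"csplus",1
"P4",2,1,"csminus",0
"P4",3,2,"csplus",1
"P4",4,2,"csminus",0
"P5",1,1,"csplus",1
"P5",2,1,"csminus",0
"P5",3,2,"csplus",1
"P5",4,2,"csminus",0
"P6",1,1,"csplus",1
"P6",2,1,"csminus",0
"P6",3,2,"csplus",1
"P6",4,2,"csminus",0
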