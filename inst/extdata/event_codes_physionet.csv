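code,label,description
T1_fist,0,left fist
T2_fist,1,right fist
T1_both,2,both fists
T2_both,3,feet
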