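code,label,description
769,0,left hand
770,1,right hand
771,2,foot
772,3,tongue
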