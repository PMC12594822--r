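duration_s,ch1_uA,ch2_uA,ch3_uA,ch4_uA,ch5_uA,ch6_uA,ch7_uA,ch8_uA,mode
21600,10,0,10,0,10,0,10,0,EF
61200,0,5,0,5,0,5,0,5,FLX
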