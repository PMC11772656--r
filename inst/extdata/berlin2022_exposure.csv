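phase,runner,position
1,Eliud Kipchoge,MAIN
1,Jacob Kiplimo,P1
1,Isiah Koech,P2
2,Eliud Kipchoge,MAIN
2,Jacob Kiplimo,P1
3,Eliud Kipchoge,MAIN
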