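phase,runner,position
1,Eliud Kipchoge,MAIN
1,Josphat Boit,P1
1,Sammy Kitwara,P2
2,Eliud Kipchoge,MAIN
2,Josphat Boit,P1
2,Sammy Kitwara,P2
3,Eliud Kipchoge,MAIN
3,Josphat Boit,P1
4,Eliud Kipchoge,MAIN
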