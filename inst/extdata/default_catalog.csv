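formation,position,a,b,c,provenance
SOLO,MAIN,0.493,-3.256,7.878,embedded solo polynomial
F1,MAIN,0.39933,-2.63736,6.3811800000000005,printed target-pace reduction (scaled solo)
F2,MAIN,0.28593999999999997,-1.8884799999999997,4.56924,printed target-pace reduction (scaled solo)
F3,MAIN,0.28593999999999997,-1.8884799999999997,4.56924,printed target-pace reduction (scaled solo)
F4,MAIN,0.22678,-1.49776,3.62388,printed target-pace reduction (scaled solo)
F5,MAIN,0.2258926,-1.4918992,3.6096996,printed reduction relative to F3 (scaled solo)
F6,MAIN,0.2258926,-1.4918992,3.6096996,printed reduction relative to F3 (scaled solo)
F11,MAIN,0.12818000000000002,-0.84656,2.04828,printed target-pace reduction (scaled solo)
F12,MAIN,0.18734,-1.23728,2.99364,printed target-pace reduction (scaled solo)
F1,P1,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F2,P1,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F2,P2,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F3,P1,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F3,P2,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F3,P3,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F4,P1,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F12,P1,0.47820999999999997,-3.15832,7.64166,synthetic pacer default (scaled solo)
F12,P2,0.22185,-1.4651999999999998,3.5451,synthetic pacer default (scaled solo)
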