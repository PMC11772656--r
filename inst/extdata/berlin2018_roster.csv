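name,role,mass_kg
Eliud Kipchoge,main,52
Josphat Boit,pacer,52
Sammy Kitwara,pacer,52
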