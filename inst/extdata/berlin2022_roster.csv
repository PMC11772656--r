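name,role,mass_kg
Eliud Kipchoge,main,52
Jacob Kiplimo,pacer,52
Isiah Koech,pacer,52
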