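cum_time,cum_distance_km,speed_mps,formation
01:04:08,22.59,5.87,F3
01:10:08,24.66,5.75,F1
02:01:09,42.195,5.728,SOLO
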