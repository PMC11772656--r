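cum_time,cum_distance_km,speed_mps,formation
00:41:17,14.23,5.744,F3
00:45:39,15.69,5.572,F2
01:14:23,25.68,5.794,F1
02:01:39,42.195,5.823,SOLO
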