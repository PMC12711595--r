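stimulus,spl_low_db,spl_high_db
drone,68,78
vehicle,55,64
talking,58,68
dove,65,73
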