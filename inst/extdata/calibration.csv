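# Calibrated constant temperatures: total egg development duration (oviposition
# to hatching) and the lower developmental threshold used for ADH accumulation.
temp_c,total_duration_h,base_temp_c
7.3,120,1
25,16,1
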