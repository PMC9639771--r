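length,condition,fascicle_length_mm,pennation_deg
short,rest,60.2,15.2
long,rest,74.5,12.0
short,mvc20,52.7,19.2
long,mvc20,66.3,16.9
short,mvc40,50.8,20.8
long,mvc40,61.9,17.4
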