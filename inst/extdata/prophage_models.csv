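phage_id,headful_size,max_headfuls,hf1_phage_carryover
80alpha,45000,7,0
P22,43000,12,0
phi11,45000,7,0
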