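mirna	seq_direction
hsa-miR-7-5p	down
hsa-miR-615-3p	down
hsa-miR-577	down
hsa-miR-98	up
hsa-miR-375	up
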