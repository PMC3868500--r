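group	unique_total	unique_mapped	reads_total	reads_mapped
MN	154580	38577	11109127	9445450
NC	1034806	539279	16001191	13301445
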