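mirna	group	ct_ref	ct_target
hsa-miR-7-5p	NC	10.88	21.61
hsa-miR-7-5p	MN	11.37	27.16
hsa-miR-615-3p	NC	10.88	17.26
hsa-miR-615-3p	MN	11.37	20.15
hsa-miR-577	NC	10.88	35.40
hsa-miR-577	MN	11.37	37.01
hsa-miR-98	NC	10.88	28.04
hsa-miR-98	MN	11.37	24.25
hsa-miR-375	NC	10.88	19.51
hsa-miR-375	MN	11.37	17.37
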