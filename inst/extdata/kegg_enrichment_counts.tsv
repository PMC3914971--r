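set_id	description	a	b	c	d
hsa04310	Wnt signaling pathway	6	32	141	2951
hsa04510	Focal adhesion	7	31	227	2865
hsa04512	ECM-receptor interaction	4	34	82	3010
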