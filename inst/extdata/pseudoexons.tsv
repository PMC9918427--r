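name	variant	chrom	start	end	intron	printed_length	note
PE8	c.1551-504C>T	chr1	216495824	216495941	8	118
PE10	c.1841-377A>G	chr1	216463130	216463223	10	94
PE20	c.4397-3890A>G	chr1	216352719	216352805	20	87
PE23	c.4885+375A>G	chr1	216261985	216262114	23	130
PE20a	c.4397-3890A>G	chr1	216356236	216356337	20	NA	optional; tentatively attributed to the c.4397-3890A>G haplotype (possibly c.4396+7263del)
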