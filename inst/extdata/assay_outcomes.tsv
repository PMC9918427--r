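variant	variant_class	effect	events	effect_classes	consequence_p	domain_disrupted	proband
c.1551-504C>T	deep_intronic	full	pseudoexon_inclusion:chr1:216495824-216495941	ptc_in_inserted	p.Arg517_Cys518ins*13	0	USH46
c.4397-3890A>G	deep_intronic	full	pseudoexon_inclusion:chr1:216352719-216352805	ptc_in_inserted	p.Ala1465_Ala1466ins*5	0	arRP36
c.4885+375A>G	deep_intronic	full	pseudoexon_inclusion:chr1:216261985-216262114	ptc_frameshift	p.Ser1629Valfs*52	0	USH32
c.1841-377A>G	deep_intronic	partial	pseudoexon_inclusion:chr1:216463130-216463223	ptc_in_inserted	p.[Thr613_Gly614ins*9,=]	0	USH49
c.1644+7453A>G	deep_intronic	none				0	USH6
c.4396+6885T>C	deep_intronic	none				0
c.6806-7599C>G	deep_intronic	none				0
c.5775A>T	noncanonical_splice	full	exon_skip:28	inframe_deletion	p.Gly1858_Thr1925del	1	USH13
c.14791+5G>T	noncanonical_splice	full	exon_skip:67	ptc_frameshift	p.Tyr4862Alafs*22	0	USH5
c.9259-9T>A	noncanonical_splice	full	exon_extension_5:7@47	ptc_frameshift	p.Val3087Phefs*4	0	USH12
c.9258G>T	noncanonical_splice	full	partial_exon_skip:153@46:3;partial_exon_skip:116@46:3	inframe_deletion,ptc_frameshift	p.[Arg3037_Val3087del,Val3049*]	1	USH37
c.14134-5T>C	noncanonical_splice	partial	exon_extension_5:47@65	ptc_frameshift	p.[=,Val4712Profs*2]	0	arRP1
c.9959-3C>G	noncanonical_splice	partial	exon_skip:51;partial_exon_skip:57@51:5	ptc_frameshift,inframe_deletion	p.[Met3321Asnfs*22,=,Gly3320_Ser3338del]	0	USH46
c.2303G>A	exonic	partial	exon_internal_deletion:129,115@13;partial_exon_skip:513@13:3	ptc_frameshift,inframe_deletion	p.[Cys766Tyrfs*3,Glu767_Gly937del,Cys768Tyr]	0	arRP21
c.4714C>T	exonic	none				0
c.8710G>A	exonic	none				0	arRP47
c.12343C>T	exonic	none				0	arRP38
c.14664G>A	exonic	none				0	arRP16
c.14753C>T	exonic	none				0	USH15
c.5573-19A>G	branchpoint	full	exon_skip:28	inframe_deletion	p.Gly1858_Thr1925del	1	arRP10
c.14583-26A>G	branchpoint	partial	exon_skip:67	ptc_frameshift	p.[=,Tyr4862Alafs*22]	0	USH23
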