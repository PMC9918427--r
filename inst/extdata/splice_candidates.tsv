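variant	is_stop_gain	is_canonical	previously_characterized	is_artifact	remains_monoallelic	predicts_canonical_gain	manual_include
c.1551-504C>T	0	0	0	0	0	0	0
c.4397-3890A>G	0	0	0	0	0	0	0
c.4885+375A>G	0	0	0	0	0	0	0
c.1841-377A>G	0	0	0	0	0	0	0
c.6806-7599C>G	0	0	0	0	0	0	1
c.1644+7453A>G	0	0	0	0	0	0	1
c.4396+6885T>C	0	0	0	0	0	0	1
c.5775A>T	0	0	0	0	0	0	0
c.14791+5G>T	0	0	0	0	0	0	0
c.9259-9T>A	0	0	0	0	0	0	0
c.9258G>T	0	0	0	0	0	0	0
c.14134-5T>C	0	0	0	0	0	0	0
c.9959-3C>G	0	0	0	0	0	0	0
c.2303G>A	0	0	0	0	0	0	0
c.4714C>T	0	0	0	0	0	0	0
c.8710G>A	0	0	0	0	0	0	1
c.12343C>T	0	0	0	0	0	0	0
c.14664G>A	0	0	0	0	0	0	0
c.14753C>T	0	0	0	0	0	0	0
c.5573-19A>G	0	0	0	0	0	0	0
c.14583-26A>G	0	0	0	0	0	0	0
c.11864G>A	1	0	0	0	0	0	0
c.7244C>G	1	0	0	0	0	0	0
c.9371+1G>C	0	1	0	0	0	0	0
c.8559-2A>G	0	1	0	0	0	0	0
c.12067-2A>G	0	1	0	0	0	0	0
c.11549-1G>A	0	1	0	0	0	0	0
c.14791+2T>C	0	1	0	0	0	0	0
c.1841-2A>G	0	1	0	0	0	0	0
c.5573-1G>T	0	1	0	0	0	0	0
c.5573-834A>G	0	0	1	0	0	0	0
c.7595-2144A>G	0	0	1	0	0	0	0
c.12295-3T>A	0	0	1	0	0	0	0
c.1551-508C>T	0	0	0	1	0	0	0
c.4732C>T	0	0	0	0	1	0	0
c.9975G>A	0	0	0	0	0	1	0
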