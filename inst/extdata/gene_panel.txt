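# Panel genes named in the cohort table (causal genes only; the full
# 17-gene USH and 62-gene arRP panels are configuration, not package data)
USH2A
ARSG
EYS
MYO7A
PEX6
PQLC2
PROM1
RPE65
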