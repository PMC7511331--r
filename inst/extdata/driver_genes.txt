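# Driver gene panel: genes recurrently mutated in cutaneous T-cell lymphoma
# (epigenetic regulation, TCR/NF-kB signalling, JAK/STAT, chromatin
# remodelling, DNA damage response and immune surveillance).
NCOR1
ARHGEF3
ZEB1
TP53
PLCG1
RFXAP
CD58
TNFRSF1B
JAK3
MAPK1
PRKCB
MTOR
NF1
DNMT3A
TET2
SMARCB1
KDM6A
SETDB2
STAT3
NFKB2
NOTCH2
CARD11
STAT5B
CDK12
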