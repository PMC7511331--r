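sample_id	compartment	tcf	path
SIMFIX	epidermis	0.85	SIMFIX_epidermis.clonotypes.tsv
SIMFIX	dermis	0.55	SIMFIX_dermis.clonotypes.tsv
SIMFIX	blood	0.2	SIMFIX_blood.clonotypes.tsv
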