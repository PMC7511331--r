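chrom	start	end	major_cn	minor_cn
chr9	194681372	203237489	2	0
chr2	75610599	89268573	2	0
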