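track	kind	chrom	start_bp	end_bp
gwas	span	20	37700000	38500000
roh	span	20	37500000	39500000
ihs	support	20	37700000	37700000
ibs	support	20	37800000	38300000
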