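marker_id	chrom	pos
ID10	chr6	8647275
ID22	chr6	8913783
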