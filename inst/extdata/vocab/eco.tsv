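id	label	vocabulary	description
ECO:0000269	experimental evidence used in manual assertion	ECO	curator-assessed experimental support
ECO:0000314	direct assay evidence used in manual assertion	ECO	direct assay support
ECO:0000353	physical interaction evidence used in manual assertion	ECO	physical interaction support
ECO:0000250	sequence similarity evidence used in manual assertion	ECO	inferred from sequence similarity
ECO:0007682	reporter gene assay evidence used in manual assertion	ECO	reporter gene assay support
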