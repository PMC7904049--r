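id	label	vocabulary	description
RO:0002213	positively regulates	RO	causal relation: the source increases the target process
RO:0002212	negatively regulates	RO	causal relation: the source decreases the target process
RO:0002211	regulates	RO	causal relation of unspecified sign
RO:0002304	causally upstream of, positive effect	RO	indirect positive causal influence
RO:0002305	causally upstream of, negative effect	RO	indirect negative causal influence
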