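id	label	vocabulary	description
BTO:0000759	liver	BTO	largest gland of the body
BTO:0000142	brain	BTO	center of the nervous system
BTO:0000089	blood	BTO	fluid connective tissue
BTO:0001103	prostate gland	BTO	gland of the male reproductive system
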