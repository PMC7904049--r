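id	label	vocabulary	description
cellosaurus:CVCL_0030	HeLa	Cellosaurus	human cervical adenocarcinoma cell line
cellosaurus:CVCL_0031	MCF-7	Cellosaurus	human breast adenocarcinoma cell line
cellosaurus:CVCL_0045	HEK293	Cellosaurus	human embryonic kidney cell line
cellosaurus:CVCL_0004	K-562	Cellosaurus	human chronic myelogenous leukemia cell line
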