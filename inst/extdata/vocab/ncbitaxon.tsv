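id	label	vocabulary	description
NCBITaxon:9606	Homo sapiens	NCBITaxon	human
NCBITaxon:10090	Mus musculus	NCBITaxon	house mouse
NCBITaxon:10116	Rattus norvegicus	NCBITaxon	Norway rat
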