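id	label	vocabulary	description
uniprot:P31750	AKT1_MOUSE	UniProt	RAC-alpha serine/threonine-protein kinase, Mus musculus
uniprot:P31749	AKT1_HUMAN	UniProt	RAC-alpha serine/threonine-protein kinase, Homo sapiens
uniprot:Q9WUA6	FOXO3_MOUSE	UniProt	Forkhead box protein O3, Mus musculus
uniprot:O43524	FOXO3_HUMAN	UniProt	Forkhead box protein O3, Homo sapiens
uniprot:P04637	P53_HUMAN	UniProt	Cellular tumor antigen p53, Homo sapiens
uniprot:P06493	CDK1_HUMAN	UniProt	Cyclin-dependent kinase 1, Homo sapiens
uniprot:P42336	PK3CA_HUMAN	UniProt	PI3-kinase catalytic subunit alpha, Homo sapiens
uniprot:Q60823	AKT2_MOUSE	UniProt	RAC-beta serine/threonine-protein kinase, Mus musculus
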