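#ID(s) interactor A	ID(s) interactor B	Alt. ID(s) interactor A	Alt. ID(s) interactor B	Alias(es) interactor A	Alias(es) interactor B	Interaction detection method(s)	Publication 1st author(s)	Publication Identifier(s)	Taxid interactor A	Taxid interactor B	Interaction type(s)	Source database(s)	Interaction identifier(s)	Confidence value(s)	Expansion method(s)	Biological role(s) interactor A	Biological role(s) interactor B	Experimental role(s) interactor A	Experimental role(s) interactor B	Type(s) interactor A	Type(s) interactor B	Xref(s) interactor A	Xref(s) interactor B	Interaction Xref(s)	Annotation(s) interactor A	Annotation(s) interactor B	Interaction annotation(s)	Host organism(s)	Interaction parameter(s)	Creation date	Update date	Checksum(s) interactor A	Checksum(s) interactor B	Interaction Checksum(s)	Negative	Feature(s) interactor A	Feature(s) interactor B	Stoichiometry(s) interactor A	Stoichiometry(s) interactor B	Identification method participant A	Identification method participant B	Biological effect of interactor A	Biological effect of interactor B	Causal regulatory mechanism	Causal statement
uniprot:Q9WUA6	uniprot:Q9WUA6	-	-	uniprot:FOXO3_MOUSE(display_short)	uniprot:FOXO3_MOUSE(display_short)	ECO:0000250(sequence similarity evidence used in manual assertion)	-	pubmed:14874920|pubmed:84417919	NCBITaxon:9606(Homo sapiens)	NCBITaxon:9606(Homo sapiens)	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	false	-	-	-	-	-	-	-	-	MI:0220(ubiquitination reaction)	MI:2240(down-regulates)
uniprot:P06493	uniprot:P06493	-	-	uniprot:CDK1_HUMAN(display_short)	uniprot:CDK1_HUMAN(display_short)	ECO:0007682(reporter gene assay evidence used in manual assertion)	-	pubmed:57583406	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	false	-	-	-	-	-	-	-	-	-	RO:0002304(causally upstream of, positive effect)
uniprot:P31750	uniprot:P31749	-	-	uniprot:AKT1_MOUSE(display_short)	uniprot:AKT1_HUMAN(display_short)	ECO:0000269(experimental evidence used in manual assertion)	-	pubmed:27602326|pubmed:95035639	NCBITaxon:10090(Mus musculus)	NCBITaxon:10090(Mus musculus)	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	false	-	-	-	-	-	-	-	-	MI:0217(phosphorylation reaction)	RO:0002305(causally upstream of, negative effect)
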