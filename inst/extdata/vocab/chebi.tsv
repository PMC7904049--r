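id	label	vocabulary	description
CHEBI:17115	L-serine	ChEBI	proteinogenic amino acid, phospho-acceptor residue
CHEBI:16857	L-threonine	ChEBI	proteinogenic amino acid, phospho-acceptor residue
CHEBI:17895	L-tyrosine	ChEBI	proteinogenic amino acid, phospho-acceptor residue
CHEBI:18019	L-lysine	ChEBI	proteinogenic amino acid, acetylation/ubiquitination site
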