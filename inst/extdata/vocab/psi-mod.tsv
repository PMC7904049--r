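id	label	vocabulary	description
MOD:00696	phosphorylated residue	PSI-MOD	residue bearing a phosphate group
MOD:00492	N6-acetylated L-lysine	PSI-MOD	lysine residue bearing an acetyl group
MOD:01148	ubiquitinylation residue	PSI-MOD	residue conjugated to ubiquitin
MOD:00599	monomethylated residue	PSI-MOD	residue bearing a single methyl group
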