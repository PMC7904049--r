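id	label	vocabulary	description
MI:2235	up-regulates	PSI-MI	positive causal regulation of the target by the source
MI:2236	up-regulates activity	PSI-MI	positive regulation of the molecular activity of the target
MI:2240	down-regulates	PSI-MI	negative causal regulation of the target by the source
MI:2241	down-regulates activity	PSI-MI	negative regulation of the molecular activity of the target
MI:0326	protein	PSI-MI	interactor type: polypeptide chain
MI:0328	small molecule	PSI-MI	interactor type: low molecular weight compound
MI:0250	gene	PSI-MI	interactor type: nucleic acid entity coding a product
MI:0320	ribonucleic acid	PSI-MI	interactor type: RNA
MI:0217	phosphorylation reaction	PSI-MI	mechanism: addition of a phosphate group
MI:0220	ubiquitination reaction	PSI-MI	mechanism: covalent attachment of ubiquitin
MI:0192	acetylation reaction	PSI-MI	mechanism: addition of an acetyl group
MI:0407	direct interaction	PSI-MI	mechanism: physical contact between molecules
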