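id	label	vocabulary	description
GO:0005634	nucleus	GO	membrane-bounded organelle housing the genome
GO:0005737	cytoplasm	GO	cell contents excluding the nucleus and plasma membrane
GO:0005886	plasma membrane	GO	membrane surrounding the cytoplasm
GO:0005739	mitochondrion	GO	organelle of oxidative energy metabolism
GO:0005576	extracellular region	GO	space external to the plasma membrane
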