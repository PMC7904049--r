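id	label	vocabulary	description
CL:0000057	fibroblast	CL	connective tissue cell secreting extracellular matrix
CL:0000084	T cell	CL	lymphocyte of the T lineage
CL:0000540	neuron	CL	electrically excitable nerve cell
CL:0000182	hepatocyte	CL	epithelial parenchymal cell of the liver
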