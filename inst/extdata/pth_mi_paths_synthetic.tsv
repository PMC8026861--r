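subject	subject_kind	object	object_kind	polarity	relation_class	ref_count
OBESITY	disease	PTH	gene	positive	regulation	5
PTH	gene	MMP9	gene	positive	regulation	6
MMP9	gene	MI	disease	positive	regulation	8
PTH	gene	CTNNB1	gene	positive	regulation	4
CTNNB1	gene	MI	disease	positive	regulation	5
PTH	gene	SYNINH1	gene	positive	regulation	3
SYNINH1	gene	MI	disease	negative	regulation	4
PTH	gene	SYNINH2	gene	positive	regulation	3
SYNINH2	gene	MI	disease	negative	regulation	3
PTH	gene	SYNREL1	gene	positive	regulation	3
SYNREL1	gene	SYNREL2	gene	negative	regulation	3
SYNREL2	gene	MI	disease	positive	regulation	3
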