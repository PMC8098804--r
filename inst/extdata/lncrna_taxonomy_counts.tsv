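direction	zone	position	n
sense	genic	intronic	66
sense	genic	exonic	0
sense	intergenic	upstream	226
sense	intergenic	downstream	235
antisense	genic	intronic	26
antisense	genic	exonic	316
antisense	intergenic	upstream	237
antisense	intergenic	downstream	223
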