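class	nt20	nt21	nt22	nt23	nt24	other
rRNA	0	7	2	0	1043	35
tRNA	6	36	4	7	605	288
snRNA	0	8	4	1	739	148
miRNA	4	58	10	1	935	23
ta-siRNA	0	4	0	0	4	0
siRNA	0	1042	248	133	65130	0
other	16	0	0	0	0	2443
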