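species	2n	karyotype	cma3
maronii	50	14sm+36st-a	1
adoketa	48	16m-sm+32st-a	1
anomala	44	18m-sm+26st-a	1
aureocephalus	44	18m-sm+26st-a	3
taenia	44	16m-sm+28st-a	1
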