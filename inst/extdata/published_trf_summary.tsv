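compartment	isotype	anticodon	total	main_region	notes
mitochondrial	Ser	GCU	3678	5' half
mitochondrial	Val	UAC	1784	3' end
mitochondrial	Lys	CUU	1606	5' half
mitochondrial	Thr	UGU	1547	5' end and 3' half
mitochondrial	Ile	GAU	795	5' end and 3' half
mitochondrial	Phe	GAA	713	3' end
mitochondrial	Gly	UCC	583	AC stem-loop
mitochondrial	Asn	GUU	403	3' end and AC stem-loop
mitochondrial	Met	CAU	316	AC stem-loop
mitochondrial	Tyr	GUA	294	5' half and AC stem-loop
mitochondrial	Asp	GUC	218	3' end and AC stem-loop
mitochondrial	Cys	GCA	144	3' half
mitochondrial	Pro	UGG	67	5' and 3' end
mitochondrial	Gln	UUG	56	5' half and AC stem-loop
mitochondrial	Leu	UAA	30	3' end
mitochondrial	Ala	UCG	6	3' end
nuclear	Gly	GCC	3674244	5' half	a,b
nuclear	Gly	CCC	749207	5' half
nuclear	Glu	CUC	280322	5' half	c
nuclear	Lys	CUU	102190	5' half
nuclear	Asp	GUC	88065	5' half
nuclear	Glu	UUC	62011	5' end	c
nuclear	His	GUG	29698	5' end
nuclear	Thr	UGU	10286	3' end
nuclear	Gly	UCC	9046	5' half	b
nuclear	SeC	UCA	6911	5' half
nuclear	Pro	CGG	6616	5' half	b,c
nuclear	Pro	UGG	5842	5' half	b,c
nuclear	Cys	GCA	3808	5' half
nuclear	Gln	CUG	3654	AC stem-loop	b,c
nuclear	Ala	CGC	3413	5' half
nuclear	Gln	UUG	2478	5' half	b,c
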