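# Lipid fragment library: hydrogenated E. coli polar-lipid classes.
# Head formulas include the glycerol backbone, both ester carbonyls and the
# phosphate; tails are the bare hydrocarbon chains (16:0 + 18:1 equivalents).
# Volumes in A^3; n_exchangeable counts labile headgroup hydrogens.
# Cardiolipin (CL) is one molecule: four chains, double glycerophosphate head.
name	class	region	H	D	C	N	O	P	volume	n_exchangeable
PE_head	PE	head	12	0	7	1	8	1	252	3
PE_tails	PE	tail	64	0	32	0	0	0	937	0
PG_head	PG	head	12	0	8	0	10	1	257	3
PG_tails	PG	tail	64	0	32	0	0	0	937	0
CL_head	CL	head	16	0	13	0	17	2	506	2
CL_tails	CL	tail	128	0	64	0	0	0	1874	0
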