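element	pattern	category	description
CAT-box	GCCACT	growth_development	meristem expression
O2-site	GATGACATGG	growth_development	zein metabolism regulation
RY-element	CATGCATG	growth_development	seed-specific regulation
GCN4_motif	TGAGTCA	growth_development	endosperm expression
HD-Zip1	CAATWATTG	growth_development	palisade mesophyll differentiation
AACA-motif	AACAAAC	growth_development	endosperm-specific negative expression
MSA-like	YCYAACGGYYA	growth_development	cell cycle regulation
ABRE	ACGTG	phytohormone	abscisic acid responsiveness
CGTCA-motif	CGTCA	phytohormone	MeJA responsiveness
TGACG-motif	TGACG	phytohormone	MeJA responsiveness
TCA-element	CCATCTTTTT	phytohormone	salicylic acid responsiveness
ARE	AAACCA	stress	anaerobic induction
MBS	CAACTG	stress	drought inducibility (MYB binding site)
LTR	CCGAAA	stress	low-temperature responsiveness
GC-motif	CCCCCG	stress	anoxic-specific inducibility
TC-rich	GTTTTCTTAC	stress	defense and stress responsiveness
ERE	ATTTCAAA	stress	estrogen/oxidative stress responsive element
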