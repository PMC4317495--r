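gene	protein_name	alias	fold	identified
ARHGEF2	Rho/rac guanine nucleotide exchange factor 2	GEF-H1	4.3	TRUE
BCAS2	Pre-mRNA-splicing factor SPF27	DAM1	1.9	TRUE
CDK5RAP2	CDK5 regulatory subunit-associated protein 2	CEP215	U	TRUE
CKAP5	Cytoskeleton-associated protein 5	Ch-TOG, XMAP215	3.4	TRUE
CLASP1	Cytoplasmic linker-associated protein 1	CLIP-associating protein 1, hOrbit1	5.1	TRUE
CLASP2	Cytoplasmic linker-associated protein 2	CLIP-associating protein 2, hOrbit2	U	TRUE
DCTN1	Dynactin subunit 1	p150-glued	1.6	TRUE
DIAPH1	Protein diaphanous homologue 1	DRF1, mDia	2.5	TRUE
DST	Dystonin	BPA	U	TRUE
DYNC1H1	Cytoplasmic dynein 1 heavy chain 1		3.1	TRUE
KIF18B	Kinesin-like protein KIF18B		U	TRUE
KIF2C	Kinesin-like protein KIF2C	MCAK	1.4	TRUE
MACF1	Microtubule-actin crosslinking factor 1	ABP620, ACF7	8.0	TRUE
MAPRE1	Microtubule-associated protein RP/EB family member 1	EB1	1.7	TRUE
MAPRE2	Microtubule-associated protein RP/EB family member 2	EB2	3.6	TRUE
APC	Adenomatous polyposis coli protein		NA	FALSE
CLIP1	CAP-Gly domain-containing linker protein 1		NA	FALSE
KIF17	Kinesin-like protein KIF17		NA	FALSE
KIF2B	Kinesin-like protein KIF2B		NA	FALSE
KNSTRN	Small kinetochore-associated protein		NA	FALSE
MAPRE3	Microtubule-associated protein RP/EB family member 3		NA	FALSE
MLPH	Melanophilin		NA	FALSE
MTUS2	Microtubule-associated tumour suppressor candidate 2		NA	FALSE
MYO5A	Unconventional myosin-Va		NA	FALSE
NAV1	Neuron navigator 1		NA	FALSE
PAFAH1B1	Platelet-activating factor acetylhydrolase IB subunit alpha		NA	FALSE
PSRC1	Proline/serine-rich coiled-coil protein 1		NA	FALSE
SLAIN2	SLAIN motif-containing protein 2		NA	FALSE
SPAG5	Sperm-associated antigen 5		NA	FALSE
SRCIN1	SRC kinase signalling inhibitor 1		NA	FALSE
STIM1	Stromal interaction molecule 1		NA	FALSE
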