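sample	gene	hgvs_c	hgvs_p	zygosity	class	disease	inheritance	consequence	evidence_tags
P49	KAT6B	c.3747delA	p.Gly1251Glufs*21	het	P	Genitopatellar syndrome	AD	frameshift	PVS1,PM2,PP4
P432	STIL	c.3835C>T	p.Arg1279Cys	het	LP	Microcephaly 7, primary	AR	missense	PM1,PM2,PP3,PP4
P432	STIL	c.2344_2347delTTGC	p.Leu782Thrfs*2	het	P	Microcephaly 7, primary	AR	frameshift	PVS1,PM2,PP4
P211	CC2D2A	c.3829T>C	p.Cys1277Arg	het	LP	Joubert syndrome 9	AR	missense	PM2,PM3,PP3,PP4
P211	CC2D2A	c.3874G>T	p.Asp1292Tyr	het	LP	Joubert syndrome 9	AR	missense	PM2,PM3,PP3,PP4
P234	KAT6B	c.3660dup	p.Arg1221*fs*1	het	P	Genitopatellar syndrome	AD	frameshift	PVS1,PM2,PP4
P246	TUBA1A	c.748G>T	p.Val250Phe	het	LP	Lissencephaly 3	AD	missense	PM1,PM2,PP2,PP3
P273	GJC2	c.1125_1135delCGGCCTCCCTG	p.Ala379Glyfs*109	het	LP	Lymphatic malformation 3	AD	frameshift	PVS1,PM2
P348	DNM1L	c.345_346delAG	p.Glu116Lysfs*6	het	LP	Encephalopathy	AD	frameshift	PVS1,PM2
P357	FGFR3	c.1948A>G	p.Lys650Glu	het	P	Thanatophoric dysplasia	AD	missense	PS1,PM1,PM2,PM5
P431	TUBA1A	c.614A>T	p.Asp205Val	het	LP	Lissencephaly 3	AD	missense	PM1,PM2,PP2,PP3
P464	PDHA1	c.923_929delAGGAAGT	p.Ser312Valfs*1	het	LP	Pyruvate dehydrogenase E1-alpha deficiency	XLD	frameshift	PVS1,PM2
P479	GLI2	c.94dup	p.Ala32Glyfs*34	het	LP	Culler-Jones syndrome; Holoprosencephaly 9	AD	frameshift	PVS1,PM2
P558	PTPN11	c.1403C>T	p.Thr468Met	het	P	Noonan syndrome 1	AD	missense	PS1,PM1,PM2,PM5
P627	NSD1	c.5177C>T	p.Pro1726Leu	het	LP	Sotos syndrome	AD	missense	PM1,PM2,PP2,PP3
P648	FOXG1	c.171_180delCCCGCCGCCG	p.Pro60Argfs*129	het	LP	Rett syndrome, congenital variant	AD	frameshift	PVS1,PM2
P730	FANCC	c.1330-1G>A		hom	LP	Fanconi anemia, complementation group C	AR	canonical_splice	PVS1,PM2
P733	SIX3	c.339G>A	p.Trp113Stop	het	P	Holoprosencephaly 2	AD	nonsense	PVS1,PM2,PP4
P836	SOX2	c.480C>G	p.Tyr160Stop	het	P	Optic nerve hypoplasia and abnormalities of CNS	AD	nonsense	PVS1,PM2,PP4
P903	OFD1	c.1103_1106delTGAT	p.Ile369Lysfs*18	het	LP	Orofaciodigital syndrome I	XLD	frameshift	PVS1,PM2
P924	ARX	c.1074-1G>A		het	LP	Lissencephaly	XL	canonical_splice	PVS1,PM2
P2942	NID1	c.1786C>T	p.Arg596*	het	LP	Dandy-Walker malformation	AD	nonsense	PVS1,PM2
P993	PDHA1	c.933_936delAAGT	p.Ser312Argfs*13	het	P	Pyruvate dehydrogenase E1-alpha deficiency	XLD	frameshift	PVS1,PM2,PP4
P1278	CC2D2A	c.4333C>T	p.Arg1445*	hom	P	Meckel syndrome 6	AR	nonsense	PVS1,PM2,PP4
P222	PTCH1	c.2757_2758delCT	p.Phe919Leufs*39	het	LP	Basal cell nevus syndrome	AD	frameshift	PVS1,PM2
P114	NF1	c.1742dup	p.Leu581Phefs*6	het	P	Neurofibromatosis, type I	AD	frameshift	PVS1,PM2,PP4
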