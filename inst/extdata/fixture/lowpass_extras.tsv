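sample	kind	event	chrom	class	category	note
P1133	aneuploidy_mosaic	possible mosaic 47,XXY	X	VUS	none	no established link to the imaging phenotype
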