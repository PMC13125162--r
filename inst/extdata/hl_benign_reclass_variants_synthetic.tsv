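chrom	pos	ref	alt	gene	hgnc	transcript	hgvs_c	dataset	moi	baseline_class	evidence
5	89938764	A	G	ADGRV1	HGNC:17416	NM_032119.4	c.2459A>G	HL	AR	VUS	BS1,BP4
1	216011445	C	T	USH2A	HGNC:12601	NM_206933.4	c.9259G>A	HL	AR	VUS	BS1,BP4
4	6279355	C	T	WFS1	HGNC:12762	NM_006005.3	c.173C>T	HL	AD	VUS	BS1,BP4
7	24784260	C	T	GSDME	HGNC:2810	NM_001127453.2	c.325G>A	HL	AD	VUS	BS1,BP4
8	61765978	A	G	CHD7	HGNC:20626	NM_017780.4	c.6694A>G	HL	AD	VUS	BS1,BP4
19	50783609	C	T	MYH14	HGNC:23212	NM_001145809.2	c.4259C>T	HL	AD	VUS	BS1,BP4
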