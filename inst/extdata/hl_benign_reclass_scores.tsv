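chrom	pos	ref	alt	REVEL	VARITY
5	89938764	A	G	0.014	
1	216011445	C	T		0.032904
4	6279355	C	T		0.021316
7	24784260	C	T		0.020728
8	61765978	A	G		0.012199
19	50783609	C	T		0.019462
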