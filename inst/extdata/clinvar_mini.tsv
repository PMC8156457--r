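pos	ref	alt	type	rsid	clinvar_id	significance	diagnoses
15301	G	A	SNV	rs193302991	140591	Conflicting interpretations of pathogenicity	Familial cancer of breast
14783	T	C	SNV	rs193302982	140588	Conflicting interpretations of pathogenicity	Familial cancer of breast
15452	C	A	SNV	rs193302994	143925	Benign	Neoplasm of ovary|Leigh syndrome
3010	G	A	SNV	rs3928306	441149	Drug response	Not provided
13708	G	A	SNV	rs28359178	9696	Benign	Leber's optic atrophy|Leigh syndrome
961	T	G	SNV	.	.	Pathogenic	Nonsyndromic sensorineural mitochondrial deafness
15511	T	C	SNV	.	.	Pathogenic	Neoplasm of ovary
951	G	A	SNV	.	.	Pathogenic	Not provided
980	T	C	SNV	.	.	Pathogenic	Not provided
1008	A	G	SNV	.	.	Pathogenic	Not provided
8410	C	T	SNV	.	.	Pathogenic	Not provided
11560	A	G	SNV	.	.	Pathogenic	Not provided
14470	T	A	SNV	.	.	Pathogenic	Not provided
15262	T	C	SNV	.	.	Pathogenic	Not provided
15514	T	C	SNV	.	.	Pathogenic	Not provided
15833	C	T	SNV	.	.	Pathogenic	Not provided
489	T	C	SNV	.	.	Likely benign	Not provided
10400	C	T	SNV	.	.	Benign	Not provided
263	A	G	SNV	.	.	Benign	Not provided
750	A	G	SNV	.	.	Benign	Not provided
2706	A	G	SNV	.	.	Benign	Not provided
15326	A	G	SNV	.	.	Benign	Not provided
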