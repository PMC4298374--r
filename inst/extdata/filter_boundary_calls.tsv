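patient_id	region_id	gene	chrom	pos	ref	alt	depth	alt_reads	consequence	in_dbsnp	is_indel
T1	R1	VHL	3	10183736	C	T	100	4	missense	FALSE	FALSE
T1	R1	VHL	3	10183801	G	A	20	1	missense	FALSE	FALSE
T1	R2	PBRM1	3	52584255	A	G	9	5	missense	FALSE	FALSE
T1	R2	SETD2	3	47057912	C	T	200	100	synonymous	FALSE	FALSE
T1	R3	KDM5C	X	53220655	G	T	100	50	missense	TRUE	FALSE
T1	R3	BAP1	3	52436282	CT	C	100	50	frameshift_indel	TRUE	TRUE
T2	R1	VHL	3	10183920	C	A	950	400	nonsense	FALSE	FALSE
T2	R1	PBRM1	3	52584301	GAA	G	80	8	inframe_indel	FALSE	TRUE
T2	R2	SETD2	3	47058101	T	C	500	250	other	FALSE	FALSE
T2	R2	VHL	3	10184002	A	T	10	1	missense	FALSE	FALSE
T2	R3	BAP1	3	52436411	G	C	8	4	missense	FALSE	FALSE
T2	R3	KDM5C	X	53220720	C	G	100	3	missense	TRUE	FALSE
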