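chain	position	dominant_aa	weak_aa	category	evidence
alpha	5	T	A	1	curated
alpha	19	V	S	2	curated
alpha	20	T	S	1	curated
alpha	24	T	A	1	curated
alpha	39	L	F	3	curated
alpha	50	M	I	2	curated
alpha	55	R	D	1	curated
alpha	86	S	H	1	curated
alpha	96	L	P	4	curated
beta	9	R	S	4	curated
beta	10	Y	N	4	curated
beta	18	I	V	2	synthetic
beta	43	Q	R	3	curated
beta	88	A	G	1	synthetic
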