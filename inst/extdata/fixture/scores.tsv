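protein_id	position	wt	mut	panther	phdsnp	sift	snap
P001	5	A	V	0.9	0.9	0.01	50
P002	5	R	W	0.8	0.7	0.02	30
P003	5	L	I	0.1	0.2	0.9	-40
P004	5	K	E	0.2	0.3	0.5	-10
P005	5	G	D	0.9	0.8	0.02	-20
P006	5	C	Y	0.6	0.7	0.01	0
P007	5	S	T	0.1	0.3	0.8	60
P008	5	F	L		0.8	0.03	40
P009	5	D	N	0.9	0.7	0.9	-50
P010	5	E	Q	0.7	0.2		30
P011	5	V	M	0.8	0.3	0.02	
P012	5	T	S	0.6		0.04	-30
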