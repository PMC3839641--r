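protein_id	position	wt	mut	f_wt	f_mut	n_al	ci
P001	5	A	V	1.000000000000000	0.000000000000000	6	1.000000000000000
P002	5	R	W	0.833333333333333	0.166666666666667	6	0.849598973565224
P003	5	L	I	0.500000000000000	0.500000000000000	6	0.768621786840241
P004	5	K	E	0.333333333333333	0.333333333333333	6	0.633274208657915
P005	5	G	D	1.000000000000000	0.000000000000000	5	1.000000000000000
P006	5	C	Y	1.000000000000000	0.000000000000000	4	1.000000000000000
P007	5	S	T	0.500000000000000	0.500000000000000	6	0.768621786840241
P008	5	F	L	0.833333333333333	0.166666666666667	6	0.849598973565224
P009	5	D	N	0.666666666666667	0.333333333333333	6	0.787526350764421
P010	5	E	Q	0.500000000000000	0.500000000000000	6	0.768621786840241
P011	5	V	M	1.000000000000000	0.000000000000000	6	1.000000000000000
P012	5	T	S	0.333333333333333	0.333333333333333	6	0.633274208657915
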