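protein_id	position	wt	mut	label
P001	5	A	V	disease
P002	5	R	W	disease
P003	5	L	I	polymorphism
P004	5	K	E	polymorphism
P005	5	G	D	disease
P006	5	C	Y	disease
P007	5	S	T	polymorphism
P008	5	F	L	disease
P009	5	D	N	disease
P010	5	E	Q	polymorphism
P011	5	V	M	polymorphism
P012	5	T	S	polymorphism
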