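>P011_query
ACDEVGHIK
>P011_h1
ACDEVGHIK
>P011_h2
ACDEVGHIK
>P011_h3
ACDEVGHIK
>P011_h4
ACDEVGHIK
>P011_h5
ACDEVGHIK
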