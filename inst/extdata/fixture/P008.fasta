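>P008_query
ACDEFGHIK
>P008_h1
ACDEFGHIK
>P008_h2
ACDEFGHIK
>P008_h3
ACDELGHIK
>P008_h4
ACDEFGHIK
>P008_h5
ACDEFGHIK
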