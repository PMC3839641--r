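>P004_query
ACDEKGHIK
>P004_h1
ACDEKGHIK
>P004_h2
ACDEEGHIK
>P004_h3
ACDEEGHIK
>P004_h4
ACDEGGHIK
>P004_h5
ACDEGGHIK
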