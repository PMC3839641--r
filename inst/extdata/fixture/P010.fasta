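>P010_query
ACDEEGHIK
>P010_h1
ACDEQGHIK
>P010_h2
ACDEEGHIK
>P010_h3
ACDEQGHIK
>P010_h4
ACDEQGHIK
>P010_h5
ACDEEGHIK
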