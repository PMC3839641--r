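>P005_query
ACDEGGHIK
>P005_h1
ACDEGGHIK
>P005_h2
ACDEGGHIK
>P005_h3
ACDEGGHIK
>P005_h4
ACDEGGHIK
>P005_h5
ACDE-GHIK
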