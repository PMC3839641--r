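>P002_query
ACDERGHIK
>P002_h1
ACDERGHIK
>P002_h2
ACDERGHIK
>P002_h3
ACDERGHIK
>P002_h4
ACDERGHIK
>P002_h5
ACDEWGHIK
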