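>P006_query
ACDECGHIK
>P006_h1
ACDECGHIK
>P006_h2
ACDECGHIK
>P006_h3
ACDECGHIK
>P006_h4
ACDE-GHIK
>P006_h5
ACDE-GHIK
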