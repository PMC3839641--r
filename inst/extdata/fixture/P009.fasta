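>P009_query
ACDEDGHIK
>P009_h1
ACDEDGHIK
>P009_h2
ACDEDGHIK
>P009_h3
ACDEDGHIK
>P009_h4
ACDENGHIK
>P009_h5
ACDENGHIK
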