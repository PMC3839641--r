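>P007_query
ACDESGHIK
>P007_h1
ACDETGHIK
>P007_h2
ACDESGHIK
>P007_h3
ACDETGHIK
>P007_h4
ACDETGHIK
>P007_h5
ACDESGHIK
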