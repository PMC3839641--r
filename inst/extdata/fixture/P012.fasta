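>P012_query
ACDETGHIK
>P012_h1
ACDESGHIK
>P012_h2
ACDEAGHIK
>P012_h3
ACDETGHIK
>P012_h4
ACDESGHIK
>P012_h5
ACDEAGHIK
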