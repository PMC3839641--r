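>P001_query
ACDEAGHIK
>P001_h1
ACDEAGHIK
>P001_h2
ACDEAGHIK
>P001_h3
ACDEAGHIK
>P001_h4
ACDEAGHIK
>P001_h5
ACDEAGHIK
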