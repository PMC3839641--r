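>P003_query
ACDELGHIK
>P003_h1
ACDEIGHIK
>P003_h2
ACDELGHIK
>P003_h3
ACDEIGHIK
>P003_h4
ACDELGHIK
>P003_h5
ACDEIGHIK
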