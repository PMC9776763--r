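truth,Positive,Negative
Positive,238,12
Negative,1,1077
Non-Tumor,5,57
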