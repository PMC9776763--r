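truth,Strong,Moderate,Weak
Strong,48,10,0
Moderate,6,86,7
Weak,0,1,80
Negative,0,0,1
Non-Tumor,1,0,4
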