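partition,enrolled,excluded
T1,150,14
T2,150,20
T3,150,19
NP,150,14
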