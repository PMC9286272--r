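variable,category,pregnant_n,nonpregnant_n
residence,rural,216,72
residence,urban,234,78
altitude,lowland,246,82
altitude,highland,204,68
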