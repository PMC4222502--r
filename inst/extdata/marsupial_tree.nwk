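(chicken:1,((M_domestica:1,D_marsupialis:1)Ameridelphia:1,(S_crassicaudata:1,(T_vulpecula:1,(M_eugenii:1,A_rufescens:1)Macropodiformes:1)Diprotodontia:1)Australidelphia:1)Marsupialia:1)Amniota;
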