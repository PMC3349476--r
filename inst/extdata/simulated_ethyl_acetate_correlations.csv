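"experiment","f1_ppm","f2_ppm","intensity","ambiguous"
"ONEBOND_CH",2.13462011113967,31.6342580972257,1,FALSE
"ONEBOND_CH",3.57663679508962,58.6439990680028,1,FALSE
"ONEBOND_CH",1.992843666469,27.2889171332486,1,FALSE
"LONGRANGE_CH",2.13462011113967,174.495418513744,1,FALSE
"LONGRANGE_CH",3.57663679508962,174.495418513744,1,FALSE
"LONGRANGE_CH",3.57663679508962,27.2889171332486,1,FALSE
"LONGRANGE_CH",1.992843666469,58.6439990680028,1,FALSE
"COSY_HH",3.57663679508962,1.992843666469,1,FALSE
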