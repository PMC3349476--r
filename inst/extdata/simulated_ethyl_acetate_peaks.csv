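"nucleus","shift_ppm","intensity","multiplicity"
"C13",27.2889171332486,1,"CH3"
"C13",31.6342580972257,1,"CH3"
"C13",58.6439990680028,1,"CH2"
"C13",174.495418513744,1,"C"
"H1",2.13462011113967,3,"unknown"
"H1",3.57663679508962,2,"unknown"
"H1",1.992843666469,3,"unknown"
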