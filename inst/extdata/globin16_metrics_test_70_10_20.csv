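class,precision,sensitivity,specificity,f1
Family01,94,94,100,94
Family02,91,91,99,91
Family03,97,95,100,96
Family04,79,91,98,84
Family05,97,96,100,97
Family06,87,88,99,88
Family07,99,95,100,97
Family08,90,94,99,92
Family09,99,92,100,95
Family10,88,90,99,89
Family11,91,87,99,89
Family12,99,96,100,97
Family13,100,97,100,99
Family14,100,99,100,99
Family15,93,99,100,96
Family16,93,96,99,94
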