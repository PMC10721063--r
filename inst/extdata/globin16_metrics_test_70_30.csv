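class,precision,sensitivity,specificity,f1
Family01,97,98,100,97
Family02,82,88,99,85
Family03,96,97,100,97
Family04,90,94,99,92
Family05,100,97,100,98
Family06,84,84,99,84
Family07,98,100,100,99
Family08,92,93,99,92
Family09,97,91,100,94
Family10,90,87,99,89
Family11,90,87,99,89
Family12,99,97,100,98
Family13,96,99,100,97
Family14,97,99,100,98
Family15,91,85,99,88
Family16,98,93,100,96
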