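class,precision,sensitivity,specificity,f1
Family01,94,94,100,94
Family02,87,87,99,87
Family03,94,94,100,94
Family04,82,87,99,84
Family05,100,100,100,100
Family06,89,81,99,85
Family07,97,97,100,97
Family08,81,84,99,83
Family09,97,97,100,97
Family10,90,87,99,88
Family11,100,90,100,95
Family12,100,94,100,97
Family13,94,100,100,97
Family14,100,100,100,100
Family15,90,84,99,87
Family16,87,84,99,85
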