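class,tp,fp,fn,tn
Family01,29,2,2,461
Family02,27,4,4,459
Family03,29,2,2,461
Family04,27,6,4,457
Family05,31,0,0,463
Family06,25,3,6,460
Family07,30,1,1,462
Family08,26,6,5,457
Family09,30,1,1,462
Family10,26,3,4,461
Family11,28,0,3,463
Family12,29,0,2,463
Family13,31,2,0,461
Family14,30,0,0,464
Family15,26,3,5,460
Family16,26,4,5,459
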