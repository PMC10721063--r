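class,tp,fp,fn,tn
Family01,114,4,2,1736
Family02,101,22,14,1719
Family03,113,5,3,1735
Family04,107,12,7,1730
Family05,112,0,4,1740
Family06,98,18,18,1722
Family07,116,2,0,1738
Family08,108,10,8,1730
Family09,105,3,11,1737
Family10,101,11,15,1729
Family11,101,11,15,1729
Family12,113,1,3,1739
Family13,113,5,1,1735
Family14,115,4,1,1736
Family15,99,10,17,1730
Family16,108,2,8,1738
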