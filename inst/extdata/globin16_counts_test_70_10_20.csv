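class,tp,fp,fn,tn
Family01,72,5,5,1153
Family02,71,7,7,1150
Family03,73,2,4,1156
Family04,70,19,7,1139
Family05,74,2,3,1156
Family06,68,10,9,1148
Family07,75,1,4,1155
Family08,72,8,5,1150
Family09,71,1,6,1157
Family10,69,9,8,1149
Family11,67,7,10,1151
Family12,74,1,3,1157
Family13,76,0,2,1157
Family14,76,0,1,1158
Family15,69,5,1,1160
Family16,75,6,3,1151
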