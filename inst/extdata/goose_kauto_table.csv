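genotype,system,k_auto,sem,n
SVA,alpha,0.109,0.017,3
GAA,alpha,0.164,0.026,3
GVP,alpha,0.399,0.067,3
SAP,alpha,0.149,0.011,3
GVA,alpha,0.424,0.036,3
SAA,alpha,0.154,0.013,3
SVP,alpha,0.159,0.009,3
GAP,alpha,0.170,0.014,3
SE,beta,0.112,0.019,3
SD,beta,0.132,0.014,3
TE,beta,0.156,0.019,3
TD,beta,0.170,0.014,3
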