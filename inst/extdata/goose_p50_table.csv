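genotype,system,p50_stripped,p50_se,dlog_kcl,dlog_ihp,dlog_kcl_ihp,n
SVA,alpha,3.42,0.06,0.115,0.749,0.643,3
GAA,alpha,3.53,0.08,0.111,0.745,0.693,3
GVP,alpha,3.68,0.01,0.072,0.742,0.584,3
SAP,alpha,3.98,0.03,0.098,0.653,0.523,3
GVA,alpha,3.52,0.04,0.079,0.708,0.589,3
SAA,alpha,3.32,0.05,0.156,0.870,0.742,3
SVP,alpha,3.88,0.04,0.027,0.691,0.573,3
GAP,alpha,4.30,0.06,0.092,0.815,0.630,3
SE,beta,4.10,0.04,0.082,0.843,0.680,3
SD,beta,4.10,0.05,0.052,0.729,0.601,3
TE,beta,4.01,0.04,0.104,0.774,0.549,3
TD,beta,4.30,0.06,0.092,0.815,0.630,3
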