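taxon,alpha18,alpha63,alpha119,beta4,beta125
Anser_indicus,S,V,A,T,D
Anser_anser,G,A,P,S,E
Anser_cygnoides,G,A,P,S,E
Anser_fabalis,G,A,P,S,E
Anser_albifrons,G,A,P,S,E
Anser_erythropus,G,A,P,S,E
Chen_caerulescens,G,A,P,T,D
Chen_rossii,G,A,P,T,D
Branta_canadensis,G,A,P,T,D
Branta_leucopsis,G,A,P,T,D
Cygnus_olor,G,A,P,T,D
Cygnus_cygnus,G,A,P,T,D
Coscoroba_coscoroba,G,A,P,T,D
Cereopsis_novaehollandiae,G,A,P,T,D
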