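((Anser_indicus,(((Anser_anser,Anser_cygnoides),Anser_fabalis),(Anser_albifrons,Anser_erythropus))),((Chen_caerulescens,Chen_rossii),((Branta_canadensis,Branta_leucopsis),((Cygnus_olor,Cygnus_cygnus),(Coscoroba_coscoroba,Cereopsis_novaehollandiae)))));
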