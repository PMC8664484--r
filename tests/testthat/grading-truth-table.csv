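complete,unimag,unipoa,ptrep,label
TRUE,absent,absent,absent,LC
TRUE,absent,absent,insig,unclassified
TRUE,absent,absent,sig,REP
TRUE,absent,insig,absent,unclassified
TRUE,absent,insig,insig,unclassified
TRUE,absent,insig,sig,REP
TRUE,absent,sig,absent,HC
TRUE,absent,sig,insig,unclassified
TRUE,absent,sig,sig,REP
TRUE,insig,absent,absent,unclassified
TRUE,insig,absent,insig,unclassified
TRUE,insig,absent,sig,unclassified
TRUE,insig,insig,absent,unclassified
TRUE,insig,insig,insig,unclassified
TRUE,insig,insig,sig,unclassified
TRUE,insig,sig,absent,unclassified
TRUE,insig,sig,insig,unclassified
TRUE,insig,sig,sig,unclassified
TRUE,sig,absent,absent,HC
TRUE,sig,absent,insig,HC
TRUE,sig,absent,sig,HC
TRUE,sig,insig,absent,HC
TRUE,sig,insig,insig,HC
TRUE,sig,insig,sig,HC
TRUE,sig,sig,absent,HC
TRUE,sig,sig,insig,HC
TRUE,sig,sig,sig,HC
FALSE,absent,absent,absent,unclassified
FALSE,absent,absent,insig,unclassified
FALSE,absent,absent,sig,unclassified
FALSE,absent,insig,absent,unclassified
FALSE,absent,insig,insig,unclassified
FALSE,absent,insig,sig,unclassified
FALSE,absent,sig,absent,LC
FALSE,absent,sig,insig,unclassified
FALSE,absent,sig,sig,unclassified
FALSE,insig,absent,absent,unclassified
FALSE,insig,absent,insig,unclassified
FALSE,insig,absent,sig,unclassified
FALSE,insig,insig,absent,unclassified
FALSE,insig,insig,insig,unclassified
FALSE,insig,insig,sig,unclassified
FALSE,insig,sig,absent,LC
FALSE,insig,sig,insig,unclassified
FALSE,insig,sig,sig,unclassified
FALSE,sig,absent,absent,LC
FALSE,sig,absent,insig,unclassified
FALSE,sig,absent,sig,unclassified
FALSE,sig,insig,absent,LC
FALSE,sig,insig,insig,unclassified
FALSE,sig,insig,sig,unclassified
FALSE,sig,sig,absent,LC
FALSE,sig,sig,insig,unclassified
FALSE,sig,sig,sig,unclassified
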