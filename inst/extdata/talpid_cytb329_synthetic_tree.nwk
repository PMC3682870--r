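(((((GalemysA1:1,GalemysA2:1):1,(GalemysB1:1,GalemysB2:1):1):1,Desmana:2):1,(Talpa:1,Mogera:1):1):1,(Scaptonyx:1,Uropsilus:1):2);
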