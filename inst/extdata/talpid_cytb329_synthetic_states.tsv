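tip	state
GalemysA1	T
GalemysA2	T
GalemysB1	A
GalemysB2	A
Desmana	A
Talpa	A
Mogera	A
Scaptonyx	S
Uropsilus	S
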