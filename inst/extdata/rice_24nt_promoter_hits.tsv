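phasirna_id	phasirna_sequence	binding_start	binding_end	promoter_location	target_gene	target_annotation
LOC_Os01g37325.1(1684)24 5'D12(+)	AUCAUGACUUGGGUAUUACGUUUC	111	134	chr2_24766608-24766807	LOC_Os02g40860.1	Casein kinase I1 (CKI1)
LOC_Os01g37325.1(1684)24 5'D10(+)	AGUCCUGGUUUGAUAAGAUUGUAA	63	86	chr2_24766608-24766807	LOC_Os02g40860.1	Casein kinase I1 (CKI1)
LOC_Os01g37325.1(1684)24 5'D9(+)	AGUAGAUUUAGGAAACCGAUACCG	39	62	chr2_24766608-24766807	LOC_Os02g40860.1	Casein kinase I1 (CKI1)
LOC_Os01g37325.1(1665)24 5'D13(+)	ACUAGUUAUAGGGGAUAACUUAUA	154	177	chr2_24766608-24766807	LOC_Os02g40860.1	Casein kinase I1 (CKI1)
LOC_Os01g37325.1(1665)24 5'D11(+)	GACUUGGGUAUUACGUUUCCCUGU	106	129	chr2_24766608-24766807	LOC_Os02g40860.1	Casein kinase I1 (CKI1)
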