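# Evidence Code Ontology — small illustrative subset for offline method
# suggestion. Columns: term_id <TAB> term_name.
ECO:0000006	experimental evidence
ECO:0000250	sequence similarity evidence used in manual assertion
ECO:0000255	match to sequence model evidence used in manual assertion
ECO:0000269	experimental evidence used in manual assertion
ECO:0000303	non-traceable author statement used in manual assertion
ECO:0000305	curator inference used in manual assertion
ECO:0000501	evidence used in automatic assertion
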