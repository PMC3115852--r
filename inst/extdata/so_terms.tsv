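# Sequence Ontology — small illustrative subset for offline term suggestion.
# Columns: term_id <TAB> term_name. Verify ids against the released ontology
# before publishing annotations.
SO:0000110	sequence_feature
SO:0000417	polypeptide_domain
SO:0000418	signal_peptide
SO:0000419	mature_protein_region
SO:0000691	cleaved_initiator_methionine
SO:0000839	polypeptide_region
SO:0001062	propeptide
SO:0001114	peptide_helix
SO:0001128	polypeptide_turn_motif
SO:0001067	polypeptide_motif
SO:0000409	binding_site
SO:0001104	catalytic_residue
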