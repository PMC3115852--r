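# PSI-MOD protein modification ontology — small illustrative subset for
# offline term suggestion. Columns: term_id <TAB> term_name.
MOD:00696	phosphorylated residue
MOD:00046	O-phospho-L-serine
MOD:00047	O-phospho-L-threonine
MOD:00048	O4'-phospho-L-tyrosine
MOD:00064	N6-acetyl-L-lysine
MOD:00693	glycosylated residue
MOD:00427	modified residue
MOD:00408	N-acetylated residue
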