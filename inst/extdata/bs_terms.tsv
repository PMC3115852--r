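# BioSapiens annotation vocabulary — SYNTHETIC subset: the BioSapiens term
# ids are not reproduced here; these placeholder ids cover the categories the
# project annotated (secondary structure, sites, variants) so that the
# type-ahead aid is testable offline. Columns: term_id <TAB> term_name.
BS:0000001	alpha_helix
BS:0000002	beta_strand
BS:0000003	coil
BS:0000010	active_site
BS:0000011	metal_binding_site
BS:0000012	disulphide_bond
BS:0000020	sequence_variant
BS:0000021	post_translational_modification
BS:0000030	transmembrane_region
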