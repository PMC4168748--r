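catalog_name	c_pos	ref	alt	protein_label
COSMIC-standin	818	T	G	F273C
COSMIC-standin	755	G	T	S252I
COSMIC-standin	789	T	G	F263L
dbSNP-standin	922	T	C	S308P
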