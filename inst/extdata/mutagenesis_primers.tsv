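variant	target_residue	ref_aa	alt_aa	c_start_forward	c_mut	forward	reverse
F273L	273	F	L	805	817	CAGTCTTCAAATCTTGGACCCATGAAGGGAGG	CCTCCCTTCAGGGGTCCAAAATTTGAAGACTG
M276L	276	M	L	805	826	CAGTCTTCAAATTTTGGACCCCTGAAGGGAG	CCTCCCTTCATGGGTCCAAGATTTGAAGACTG
F281L	281	F	L	825	841	CATGAAGGGAGGAAATCTTGGAGGCAGAAGCTC	GAGCTTCTGCCTCCAAGATTTCCTCCCTTCATG
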