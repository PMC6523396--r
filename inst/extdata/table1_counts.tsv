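type	total	n_snp	n_indel
detected	2214448	NA	NA
reliable	1303054	1102109	200945
after_processing	226702	181567	45135
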