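snp_id	gene	allele_major	allele_minor	case_hom_major	case_het	case_hom_minor	case_n_missing	control_hom_major	control_het	control_hom_minor	control_n_missing
rs610604	TNFAIP3	T	G	553	108	6	0	553	106	8	0
rs10499194	TNFAIP3	C	T	617	50	0	0	588	79	0	0
rs13207033	TNFAIP3	G	A	544	113	10	0	517	139	11	0
rs2230926	TNFAIP3	T	G	621	46	0	0	614	51	2	0
rs6920220	TNFAIP3	G	A	660	7	0	0	662	5	0	0
rs2233287	TNIP1	G	A	662	5	0	0	667	0	0	0
rs4958881	TNIP1	T	C	563	99	5	0	560	100	7	0
rs3792783	TNIP1	A	G	392	246	29	0	398	234	35	0
rs6889239	TNIP1	C	T	382	242	43	0	375	250	42	0
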