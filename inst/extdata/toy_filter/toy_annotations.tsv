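variant_id	gene	impact	consequence	gnomad_af	cadd_phred
V01	FG01	MODERATE	missense_variant		26
V02	FG02	HIGH	missense_variant		27
V03	FG03	MODERATE	missense_variant		28
V04	FG04	HIGH	missense_variant		29
V05	FG05	MODERATE	missense_variant		30
V06	FG06	MODERATE	missense_variant		26
V07	FG01	MODERATE	missense_variant		31
V08	FG02	HIGH	stop_gained		19.9
V09	FG03	HIGH	stop_gained		19.9
V10	FG04	HIGH	stop_gained		19.9
V11	FG05	HIGH	stop_gained		
V12	FG06	HIGH	stop_gained		
V13	FG01	HIGH	stop_gained		
V14	FG02	LOW	splice_region_variant		25
V15	FG03	MODIFIER	splice_region_variant		25
V16	FG04	LOW	splice_region_variant		25
V17	FG05	MODIFIER	splice_region_variant		25
V18	FG06	LOW	splice_region_variant		25
V19	FG01	MODIFIER	splice_region_variant		25
V20	FG02	MODERATE	missense_variant	5e-05	28
V21	FG03	MODERATE	missense_variant	5e-05	28
V22	FG04	MODERATE	missense_variant	5e-05	28
V23	FG05	MODERATE	missense_variant	5e-05	28
V24	FG06	MODERATE	missense_variant	5e-05	28
V25	FG01	MODERATE	missense_variant	5e-05	28
V26	FG02	MODERATE	missense_variant	5e-04	28
V27	FG03	MODERATE	missense_variant	5e-04	28
V28	FG04	MODERATE	missense_variant	5e-04	28
V30	FG06	HIGH	stop_gained		30
V31	FG01	HIGH	stop_gained		30
V32	FG02	HIGH	stop_gained		30
V33	FG03	HIGH	stop_gained		30
V34	FG04	HIGH	stop_gained		30
V35	FG05	HIGH	stop_gained		30
V36	FG06	HIGH	stop_gained		30
V37	FG01	HIGH	stop_gained		30
V38	FG02	HIGH	stop_gained		30
V39	FG03	HIGH	stop_gained		30
V40	FG04	HIGH	stop_gained		30
V41	FG05	HIGH	stop_gained		30
V42	FG06	LOW	synonymous_variant	0.02	3
V43	FG01	LOW	synonymous_variant	0.04	3
V44	FG02	LOW	synonymous_variant	0.06	3
V45	FG03	LOW	synonymous_variant	0.08	3
V46	FG04	LOW	synonymous_variant	0.1	3
V47	FG05	LOW	synonymous_variant	0.12	3
V48	FG06	LOW	synonymous_variant	0.14	3
V49	FG01	LOW	synonymous_variant	0.16	3
V50	FG02	LOW	synonymous_variant	0.01	2
V51	FG03	LOW	synonymous_variant	0.01	2
V52	FG04	LOW	synonymous_variant	0.01	2
V53	FG05	LOW	synonymous_variant	0.01	2
V54	FG06	MODERATE	missense_variant	0.5	15
V55	FG01	MODERATE	missense_variant	0.5	15
V56	FG02	MODERATE	missense_variant	0.5	15
V57	FG03	MODERATE	missense_variant	0.5	15
V58	FG03	HIGH	stop_gained		22
V59	FG04	HIGH	frameshift_variant		33
V60	FG05	HIGH	stop_gained		30
V07	FG01	LOW	non_coding_transcript_variant		31
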