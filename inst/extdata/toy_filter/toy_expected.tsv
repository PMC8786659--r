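variant_id	gene	pathogenic	subsidiary	synonymous
V01	FG01	TRUE	TRUE	FALSE
V02	FG02	TRUE	TRUE	FALSE
V03	FG03	TRUE	TRUE	FALSE
V04	FG04	TRUE	TRUE	FALSE
V05	FG05	TRUE	TRUE	FALSE
V06	FG06	TRUE	TRUE	FALSE
V07	FG01	TRUE	TRUE	FALSE
V08	FG02	FALSE	FALSE	FALSE
V09	FG03	FALSE	FALSE	FALSE
V10	FG04	FALSE	FALSE	FALSE
V11	FG05	FALSE	FALSE	FALSE
V12	FG06	FALSE	FALSE	FALSE
V13	FG01	FALSE	FALSE	FALSE
V14	FG02	FALSE	FALSE	FALSE
V15	FG03	FALSE	FALSE	FALSE
V16	FG04	FALSE	FALSE	FALSE
V17	FG05	FALSE	FALSE	FALSE
V18	FG06	FALSE	FALSE	FALSE
V19	FG01	FALSE	FALSE	FALSE
V20	FG02	FALSE	TRUE	FALSE
V21	FG03	FALSE	TRUE	FALSE
V22	FG04	FALSE	TRUE	FALSE
V23	FG05	FALSE	TRUE	FALSE
V24	FG06	FALSE	TRUE	FALSE
V25	FG01	FALSE	TRUE	FALSE
V26	FG02	FALSE	FALSE	FALSE
V27	FG03	FALSE	FALSE	FALSE
V28	FG04	FALSE	FALSE	FALSE
V29	FG05	FALSE	FALSE	FALSE
V30	FG06	FALSE	FALSE	FALSE
V31	FG01	FALSE	FALSE	FALSE
V32	FG02	FALSE	FALSE	FALSE
V33	FG03	FALSE	FALSE	FALSE
V34	FG04	FALSE	FALSE	FALSE
V35	FG05	FALSE	FALSE	FALSE
V36	FG06	FALSE	FALSE	FALSE
V37	FG01	FALSE	FALSE	FALSE
V38	FG02	FALSE	FALSE	FALSE
V39	FG03	FALSE	FALSE	FALSE
V40	FG04	FALSE	FALSE	FALSE
V41	FG05	FALSE	FALSE	FALSE
V42	FG06	FALSE	FALSE	TRUE
V43	FG01	FALSE	FALSE	TRUE
V44	FG02	FALSE	FALSE	TRUE
V45	FG03	FALSE	FALSE	TRUE
V46	FG04	FALSE	FALSE	TRUE
V47	FG05	FALSE	FALSE	TRUE
V48	FG06	FALSE	FALSE	TRUE
V49	FG01	FALSE	FALSE	TRUE
V50	FG02	FALSE	FALSE	FALSE
V51	FG03	FALSE	FALSE	FALSE
V52	FG04	FALSE	FALSE	FALSE
V53	FG05	FALSE	FALSE	FALSE
V54	FG06	FALSE	FALSE	FALSE
V55	FG01	FALSE	FALSE	FALSE
V56	FG02	FALSE	FALSE	FALSE
V57	FG03	FALSE	FALSE	FALSE
V58	FG03	TRUE	TRUE	FALSE
V59	FG04	TRUE	TRUE	FALSE
V60	FG05	FALSE	FALSE	FALSE
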