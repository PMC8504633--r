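query_id	subject_id	q_cluster	s_cluster	q_start	q_end	s_start	s_end	q_aln	s_aln	probability	rmsd	tm_score	identity	q_scop	s_scop
d1g3qa_	d3lz6a_	4	7	5	39	2	36	TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVP	FECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFC	85	2.1	0.22	18	c.37.1.10	c.2.1.2
d1wa5a_	d2dfda1	2	3	10	111	4	107	VTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYR--CLNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWF	RGSLHKKDVRRYSAGMKYPFMRCGAQSTMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFVHPCDARYMKLHWVNLKWR	81.7	2.89	0.25	14	c.37.1.8	c.2.1.5
d2g0ta1	d2yv1a1	2	5	6	36	3	33	QDYLCTVWQTLFPVWWLSCEHAQYWNWGNL	HWCGKMGFQLRAKLTNAMEDGFLYCEYKQQ	75	2.5	0.2	21	c.37.1.10	c.2.1.6
d2g0ta1	d2yv1a1	13	5	40	68	3	31	DVLAIYFGQEKISNLQMCSQRTGWLPGA	MPLPRTRIEGLYSNSWDHDLLHWPLQMP	72	2.7	0.28	16	c.37.1.10	c.2.1.6
d9kkka_	d1t1ra2	1	2	8	37	5	34	DLWCHYMMAGLKNPVRAMIPQCGPDPSWS	PPIPGGIFKLMAREHMLIDPYSIDKSMPH	78	2.4	0.15	24	c.2.1.7	c.2.1.3
d3lz6a_	d2dfda1	7	3	12	52	9	49	VHFYVHTDSIWVLRNDYSLCIAPHMMPFCRFQFTVTVHPC	NDYIYQAQVCFLNDVVVRAIWIYWCYWMRVILCETNYWHK	90	1.5	0.1	30	c.2.1.2	c.2.1.5
d1t1ra2	d3lz6a_	2	7	0	10	0	10	WMMNTCYHTE	PWATECIDPC	71.5	2.95	0.29	20	c.2.1.3	c.2.1.2
d9aaaa_	d9bbba_	1	1	3	23	3	23	EKMLQAAQYMKWFCKDNCSV	TYIIWRGDAREKAMGYQKGN	70	2	0.2	25	c.2.1.4	c.2.1.4
d9ccca_	d9ddda_	1	1	3	28	3	28	TMKVMWAMTTIMVAGCQFAVERHQL	DHFGFVKDDKPHLTCYTNGWLSALH	95	3	0.2	22	c.2.1.5	c.2.1.5
d9eeea_	d9fffa_	1	1	3	33	3	33	CEYIRQTFTTSYGDQKNKQDEDHAFEINNN	RKDDKHNPTRRYDPWCFKVAEVFDLHQLLK	88	2	0.3	19	c.2.1.6	c.2.1.6
d9ggga_	d9hhha_	1	1	3	11	3	11	HGYIFWYM	THLNEYDA	80	2.2	0.1	28	c.2.1.2	c.2.1.3
d2g0ta1	d9iiia_	2	1	0	201	0	201	SFWTMAAVDFHGSPAWVLQLCSKTCRIDCTDMFADQGSLIKDCGCSKFTNYEGCDVTVMIHYAWSIYVLLWPNIGHHFAWMCVLGENGTQAMYWFDPWVYQCAQHRGNYMLTLWLKIWHSISMLYVSIFVRCALKATPGNWAMSQWFIWSNRHARIGMCAYFFMTTTWPVLDTLAMPQPHIEQFYWQWRSDCGHLPLLDYT	VTLLIPIYFTKIWPANAGWPWFPQQYNYIMQCQLCLDCLRWNVVMKIKIDILLCMLSYCLQWESRMWLCFWMVYMLFPLTDQLCFNRGAPKQNVHSNNGWVCIARVQAGWEAAARVMALYKFGMFWGISTNLIIHQRRMLWVRRWPYDLSPVAKMFQDFMQSFIGEFNVHPLSECNPARYNRSTTATLDTEMHLSHDVMFS	60	3.5	0.4	9	c.37.1.10	c.2.1.2
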