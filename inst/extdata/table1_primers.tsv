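name	sequence	direction	targets	aa_motif	aa_motif_printed	product_len	tier	region	notes
HoxF1	TNGARYTNGARAARGARTTYCA	forward	PG1-PG7	LELEKEFH	LELEKEFH	125	general	homeobox	universal for PG1-PG7
HoxF1N1	CARACNYTNGARYTNGARAARGARTT	forward	PG1-PG10	QTLELEKEF	QTLELEKEF	128	general	homeobox	universal for PG1-PG10
HoxF1N2	CARGTNACNGARYTNGARAARGARTT	forward	PG1-PG10	QVTELEKEF	QLTELEKEF	128	general	homeobox	universal for PG1-PG10; printed motif is inconsistent with the oligo (GTN encodes V)
HoxF7S	CARACNTAYACNMGNTAYCARAC	forward	PG5-PG7	QTYTRYQT	QTYTRYQT	149	general	homeobox	universal for PG5-PG7
HoxF8	TNGARAARGARTTYYTNTTYAA	forward	PG8-PG10	LEKEFLFN	LEKEFLFN	120	general	homeobox	universal for PG8-PG10
HoxF8N	TNGARYTNGARAARGARTTYYT	forward	PG8-PG10	LELEKEFL	LELEKEFL	125	general	homeobox	universal for PG8-PG10
HoxF9	DSNMGNAARAARVGNTGYCCNTA	forward	PG9-PG11	TRKKRCPY	TRKKRCPY	164	general	homeobox	universal for PG9-PG11
HoxF1S	AAYTTYACNACNAARCARYTNAC	forward	PG1	NFTTKQLT	NFTTKQLT	149	pg_specific	homeobox	universal for PG1
HoxF2S	MGGACNGCNTAYACNAAYACNCA	forward	PG2	RTAYTNTQ	RTAYTNTQ	152	pg_specific	homeobox	specific for PG2
HoxF3S	GCNTAYACNAGYGCNCARYTNGT	forward	PG3	AYTSAQLV	AYTSAQLV	149	pg_specific	homeobox	specific for PG3
HoxF3S1	MGVCCNMGVMGVBTNGARATGGC	forward	PG3	RPRRVEMA	RPRRVEMA	80	pg_specific	homeobox	specific for PG3
HoxF4S	ACNGCNTAYACNMGNCARCARGT	forward	PG4	TAYTRQQV	TAYTRQQV	152	pg_specific	homeobox	specific for PG4
HoxF5S	GGNAARMGSGCNMGSACNGC	forward	A5,B5	GKRARTA	GKRARTA	165	pg_specific	homeobox	specific for A5, B5
HoxFC5	AARCGNTCYMGAACNAGYTAYAC	forward	C5	KRSRTSYT	KRSRTSYT	160	member_specific	homeobox	specific for C5
HoxF8S	GARAARGARTTYYTNTTYAAYCC	forward	PG8	EKEFLFNP	EKEFLFNP	116	pg_specific	homeobox	specific for PG8
HoxF9S	GARAARGARTTYYTNTTYAAYATG	forward	PG9	EKEFLFNM	EKEFLFNM	116	pg_specific	homeobox	specific for PG9
HoxF10S	AARMGNTGYCCNTAYACNAARCA	forward	PG10	KRCPYTKH	KRCPYTKH	152	pg_specific	homeobox	specific for PG10
HoxF11	GARYTNGARMGNGARTTYTTYTT	forward	PG11	ELEREFFF	ELEREFFF	122	pg_specific	homeobox	specific for PG11
HoxF12	DSNMGNAARAARVGNAARCCNTA	forward	PG12	SRKKRKPY	SRKKRKPY	164	pg_specific	homeobox	specific for PG12
HoxF12C	AARCCNTAYTCNAARYTNCARAT	forward	C12	KPYSKLQL	KPYSKLQL	149	member_specific	homeobox	specific for C12
HoxF12D	AARCCNTAYACNAARCARCARAT	forward	D12	KPYTKQQI	KPYTKQQI	149	member_specific	homeobox	specific for D12
HoxF12N1	KCNMGVAARAARMGVAARCCSTA	forward	PG12	SRKKRKPY	SRKKRKPY	164	pg_specific	homeobox	specific for PG12
HoxF12N2	KCNMGVAARAARMGVAARCCWTA	forward	PG12	SRKKRKPY	SRKKRKPY	164	pg_specific	homeobox	specific for PG12
HoxF12N3	KCNMGVAARAARMGVAARACNTA	forward	PG12	SRKKRKTY	SRKKRKTY	164	pg_specific	homeobox	specific for PG12
HoxF13A	GGNMGNAARAARMGNGTNCCNTA	forward	A13,C13,D13,A14	GRKKRVPY	GRKKRVPY	164	pg_specific	homeobox	specific for PG13(A,C,D); also paired with HoxR14 for PG14
HoxF13B	GGNMGNAARAARMGNATHCCNTA	forward	B13	GRKKRIPY	GRKKRIPY	164	pg_specific	homeobox	specific for PG13(B)
HoxF13A1	CARYTRAARGARCTNGARMGNGARTA	forward	A13	QLKELEREY	QLKELEREY	128	member_specific	homeobox	specific for PG13(A)
HoxF13B1	CARYTRAARGARCTNGARAANGARTA	forward	B13,C13,D13	QLKELENEY	QLKELENEY	128	member_specific	homeobox	specific for PG13(B,C,D)
HoxR1	TTCATNCKNCKRTTYTGRAACCA	reverse	PG1-PG12	WFQNRRMK	WFQNRRMK	--	general	homeobox	universal for PG1-PG12
HoxR13	TTNACNCKNCKRTTYTGRAACCA	reverse	PG13	WFQNRRVK	WFQNRRVK	--	pg_specific	homeobox	specific for PG13
HoxR14	TCNGGNGTNAGRAANCGRTTYTC	reverse	PG14	ENRFLTPE	ENRFLTPE	89	pg_specific	homeobox	specific for PG14, used with HoxF13A/HoxF13B
HoxB1(5'E1)F	GACATASTRYCNAAAGGTTGTAG	forward	B1	5' UTR	5' UTR	590-630	member_specific	exon1	forward primer for HoxB1
HoxB1(E1)R	TTAACYTTCATCCANTCRAANGT	reverse	B1	TFDWMKVK	TFDWMKVK	--	member_specific	exon1	reverse primer for HoxB1
Hox2S(E1)F	GAATTYGAGMGRGARATHGGNTT	forward	PG2	EFEREIGF	EFEREIGF	270-300	pg_specific	exon1	forward primer for PG2
Hox2S(E1)R	YTTYTTCTCYTTCATCCANGG	reverse	PG2	PWMKEKK	PWMKEKK	--	pg_specific	exon1	reverse primer for PG2
Hox3S(E1)F	ATGCARAAARCRRCNTAYTAYGA	forward	PG3	MQKATYYD	MQKATYYD	400-480	pg_specific	exon1	forward primer for PG3
HoxC3(E1)F	ATGCAAAARGSTCYYTAYTAYGA	forward	C3	MQKGPYYE	MQKGPYYE	400-480	member_specific	exon1	forward primer for HoxC3
HoxA3(E1)F	GCGACCTACTAYGAYAGYTCNGC	forward	A3	ATYYDSSA	ATYYDSSA	390-470	member_specific	exon1	forward primer for HoxA3
HoxD3(E1)F	ATGCAGAAARCNGCYTAYTAYGA	forward	D3	MQKTAYYD	MQKTAYYD	400-480	member_specific	exon1	forward primer for HoxD3
Hox3S(E1)R	TCYTTCATCCANGGRAADATNTG	reverse	PG3	QIFPWMKE	QIFPWMKE	--	pg_specific	exon1	reverse primer for PG3
HoxB6(5'E1)F	AWACTRCTAATAGCTAAASCRCT	forward	B6	5' UTR	5' UTR	480-510	member_specific	exon1	reverse primer for HoxB6 (as printed)
Hox6S(E1)R	GARTTCATCCKYTGCATCCANGG	reverse	PG6	PWMQRMNS	PWMQRMNS	--	pg_specific	exon1	reverse primer for PG6
HoxB7(5'E1)F	CTCGTAAAACCGACACTAAAACG	forward	B7	5' UTR	5' UTR	440-460	member_specific	exon1	forward primer for HoxB7
Hox7S(E1)R	CATCCARGGGTADATNCGRAA	reverse	PG7	FRIYPWM	FRIYPWM	--	pg_specific	exon1	reverse primer for PG7
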