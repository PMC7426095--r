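group	member	X	Y	Z
15	1	LR
15	2	pLR
16	1	R
16	2	pR
16	3	ppR
16	4	pppR
16	5	LR
16	6	pLR
16	7	ppLR
16	8	pppLR
21	1	LRGibg	LR
21	2	RGibg	R
22	1	R
22	2	LR
23	1	R
23	2	pR
23	3	ppR
23	4	LR
23	5	pLR
23	6	ppLR
35	1	GsaGTP		GsaGTPCaMCa4
35	2			CaMCa4
36	1	AC1GsaGTPCaMCa4		AC1GsaGTPCaMCa4ATP
36	2	AC1CaMCa4		AC1CaMCa4ATP
36	3	AC1GiaGTPCaMCa4		AC1GiaGTPCaMCa4ATP
36	4	AC8CaMCa4		AC8CaMCa4ATP
38	1	AC1CaMCa4	GsaGTP	AC1GsaGTPCaMCa4
38	2	AC1CaMCa4	GiaGTP	AC1GiaGTPCaMCa4
39	1	AC8CaMCa4ATP		AC8CaMCa4
44	1	CaMCa2		CaMCa3
44	2	PP2BCaMCa2		PP2BCaMCa3
45	1	CaMCa3		CaMCa4
45	2	PP2BCaMCa3		PP2BCaMCa4
48	1	2		CaMCa2
48	2	3		CaMCa3
48	3	4		CaMCa4
53	1	p
53	2	pCaMCa4
57	1			PP1
57	2	CaMCa4		CaMCa4PP1
58	1	PP1
58	2	CaMCa4PP1		CaMCa4
64	1			Ip35PP2BCaMCa4
64	2	PP1		Ip35PP1PP2BCaMCa4
65	1	Ip35PP2BCaMCa4		PP2BCaMCa4
65	2	Ip35PP1PP2BCaMCa4		PP1PP2BCaMCa4
67	1			_PKAc
68	1	_PKAc	_S845
68	2	_S831_PKAc	_S845_S831
69	1	_memb	CaMCa4	_memb_CKCaMCa4
69	2	_memb_S845	CaMCa4	_memb_S845_CKCaMCa4
70	1	_memb_CKCaMCa4	_memb_S831	CaMCa4
70	2	_memb_S845_CKCaMCa4	_memb_S845_S831	CaMCa4
71	1	_memb	CKpCaMCa4	_memb_CKpCaMCa4
71	2	_memb	PKCt	_memb_PKCt
71	3	_memb	PKCp	_memb_PKCp
71	4	_memb_S845	CKpCaMCa4	_memb_S845_CKpCaMCa4
71	5	_memb_S845	PKCt	_memb_S845_PKCt
71	6	_memb_S845	PKCp	_memb_S845_PKCp
72	1	_memb_CKpCaMCa4	_memb_S831	CKpCaMCa4
72	2	_memb_PKCt	_memb_S831	PKCt
72	3	_memb_PKCp	_memb_S831	PKCp
72	4	_memb_S845_CKpCaMCa4	_memb_S845_S831	CKpCaMCa4
72	5	_memb_S845_PKCt	_memb_S845_S831	PKCt
72	6	_memb_S845_PKCp	_memb_S845_S831	PKCp
73	1	_S831		_S831_PKAc
74	1	_memb_S845		_memb_S845_PP1
74	2	_memb_S845_S831		_memb_S845_S831_PP1
74	3	_S845		_S845_PP1
74	4	_S845_S831		_S845_S831_PP1
75	1	_memb_S845_PP1	_memb
75	2	_memb_S845_S831_PP1	_memb_S831
75	3	_S845_PP1	
75	4	_S845_S831_PP1	_S831
76	1	_memb_S831		_memb_S831_PP1B
76	2	_memb_S845_S831		_memb_S845_S831_PP1B
76	3	_S831		_S831_PP1B
76	4	_S845_S831		_S845_S831_PP1B
77	1	_memb_S831_PP1B	_memb
77	2	_memb_S845_S831_PP1B	_memb_S845
77	3	_S831_PP1B	
77	4	_S845_S831_PP1B	_S845
78	1	_memb_S845		_memb_S845_PP2B
78	2	_memb_S845_S831		_memb_S845_S831_PP2B
78	3	_S845		_S845_PP2B
78	4	_S845_S831		_S845_S831_PP2B
79	1	_memb_S845_PP2B	_memb
79	2	_memb_S845_S831_PP2B	_memb_S831
79	3	_S845_PP2B	
79	4	_S845_S831_PP2B	_S831
80	1
80	2	_S831
81	1
81	2	_S831
88	1	PDE4	PKAc	PDE4
88	2	PDE4cAMP	PKAc	PDE4cAMP
89	1	PDE4
89	2	PDE4cAMP	cAMP
108	1	GqaGTP
108	2	CaGqaGTP	Ca
124	1	_memb	t	_memb_PKCt
124	2	_memb	p	_memb_PKCp
125	1	_memb_PKCt	_memb_S880	t
125	2	_memb_PKCp	_memb_S880	p
126	1	_S880		_S880_PP2A
127	1	_S880_PP2A
128	1
129	1
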