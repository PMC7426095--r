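dataset	pathway	origin	freq_hz	n_trains	pulses_per_train	pulse_width_ms	experiment	manipulation	target_10	target_15	target_20	sd	camkii_excludable
EC-1	horizontal	mostly post	100	1	100	3	control	none	1.3	1.4	1.3	0.1	FALSE
EC-1	horizontal	mostly post	100	1	100	3	CaMKII blocked	camkii_blocked	1.05	1.02	0.95	0.07	FALSE
EC-1	horizontal	mostly post	100	1	100	3	without post-syn. Ca	no_ca	1.05	1.05	1.1	0.09	FALSE
EC-2	ascending	mostly post	100	1	100	3	control	none	1.6	1.6	1.6	0.11	FALSE
EC-2	ascending	mostly post	100	1	100	3	PKA blocked	pka_blocked	1.4	1.4	1.4	0.13	FALSE
EC-2	ascending	mostly post	100	1	100	3	without post-syn. Ca	no_ca	1.3	1.4	1.4	0.13	FALSE
PFC-1	CC-PFC	n/a	312	1	156	3	control	none	2.0	1.98	1.9	0.08	FALSE
PFC-1	CC-PFC	n/a	312	1	156	3	without beta-adrenergic ligand	no_beta	1.34	1.4	1.36	0.09	FALSE
PFC-2	CC-PFC	n/a	312	1	156	3	control	none	1.7	1.6	1.64	0.12	FALSE
PFC-2	CC-PFC	n/a	312	1	156	3	without beta-1-receptor agonist	no_beta	1.43	1.45	1.43	0.1	FALSE
BC	L4-L2/3	n/a	5	10	4	3	control	none	1.35	1.4	1.3	0.09	FALSE
BC	L4-L2/3	n/a	5	10	4	3	CaMKII mutant	camkii_blocked	1.25	1.2	1.1	0.09	FALSE
ACC	L5/6-L2/3	post	5	10	4	3	control	none	1.55	1.4	1.4	0.05	FALSE
ACC	L5/6-L2/3	post	5	10	4	3	without s845	s845_deficient	1.1	1.05	1.05	0.07	FALSE
ACC	L5/6-L2/3	post	5	10	4	3	without s831	s831_deficient	1.35	1.4	1.3	0.1	FALSE
PFC-3	L2/3-L2/3	mostly post	0.1	1	50	3	control	none	1.3	1.4	1.4	0.14	FALSE
PFC-3	L2/3-L2/3	mostly post	0.1	1	50	3	without beta-1-receptor agonist	no_beta	1.1	1.2	1.2	0.13	FALSE
VC-1	L4-L3	n/a	5	10	4	3	CTR HFS	none	1.3	1.26	1.26	0.07	FALSE
VC-1	L4-L3	n/a	5	10	4	3	without CaMKII HFS	camkii_blocked	1.02	1.02	1.02	0.02	TRUE
VC-1	L4-L3	n/a	1	1	180	15	CTR LFS	none	NA	0.95	0.95	0.05	FALSE
VC-1	L4-L3	n/a	1	1	180	15	without CaMKII LFS	camkii_blocked	NA	0.88	0.93	0.03	TRUE
VC-2	L4-L3	n/a	5	10	4	3	CTR HFS	none	1.2	1.18	1.18	0.05	FALSE
VC-2	L4-L3	n/a	5	10	4	3	without CaMKII HFS	camkii_blocked	1.07	1.09	1.08	0.03	TRUE
VC-2	L4-L3	n/a	1	1	180	15	CTR LFS	none	NA	0.79	0.82	0.03	FALSE
VC-2	L4-L3	n/a	1	1	180	15	without CaMKII LFS	camkii_blocked	NA	0.82	0.89	0.03	TRUE
AuC-1	L6-L5	n/a	1	25	5	3	LTP-expressing cells	none	1.98	1.58	1.93	0.19	FALSE
AuC-2	L6-L5	n/a	1	25	5	3	LTD-expressing cells	none	0.77	0.68	0.67	0.09	FALSE
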