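mam	mam_length_mbp	hsa	gga	frac_mam	frac_gga
MAM1	414	2q-3pq-11qt-13-15a-21-Xp	GGA1	0.25	0.30
MAM1	414	2q-3pq-11qt-13-15a-21-Xp	GGA7	0.25	1.00
MAM1	414	2q-3pq-11qt-13-15a-21-Xp	GGA9	0.25	1.00
MAM1	414	2q-3pq-11qt-13-15a-21-Xp	GGA24	0.25	1.00
MAM2	354	5pq-6pt-8q-9pq-18	GGA2	0.60	0.70
MAM2	354	5pq-6pt-8q-9pq-18	GGAZ	0.40	0.60
MAM3	309	2p-4-6p-8p-20	GGA3	0.25	0.60
MAM3	309	2p-4-6p-8p-20	GGA4	0.25	0.70
MAM3	309	2p-4-6p-8p-20	GGA20	0.20	1.00
MAM3	309	2p-4-6p-8p-20	GGA22	0.15	1.00
MAM3	309	2p-4-6p-8p-20	GGAZ	0.15	0.40
MAM4	269	1pq-6pq	GGA1	0.20	0.30
MAM4	269	1pq-6pq	GGA3	0.15	0.40
MAM4	269	1pq-6pq	GGA8	0.15	1.00
MAM4	269	1pq-6pq	GGA21	0.10	0.50
MAM4	269	1pq-6pq	GGA23	0.10	0.50
MAM4	269	1pq-6pq	GGA25	0.15	1.00
MAM4	269	1pq-6pq	GGA26	0.15	1.00
MAM5	274	1q-3p-7pq-10p-12pq-22b	GGA1	0.55	0.40
MAM5	274	1q-3p-7pq-10p-12pq-22b	GGA2	0.45	0.30
MAM6	133	14-15b	GGA5	0.60	0.55
MAM6	133	14-15b	GGA10	0.40	1.00
MAM7	76	10q	GGA6	1.00	1.00
MAM8	52	11pq	GGA5	1.00	0.40
MAM9	44	16q-19q	GGA11	1.00	1.00
MAM10	42	7q-17pq	GGA18	0.60	1.00
MAM10	42	7q-17pq	GGA27	0.40	1.00
MAM11	41	3p-9q	GGA12	1.00	1.00
MAM12	38	5qt	GGA13	1.00	1.00
MAM13	35	1pt	GGA21	0.55	0.50
MAM13	35	1pt	GGA23	0.45	0.50
MAM14	31	12qt-22a	GGA15	1.00	1.00
MAM15	29	7pt-16p-17p	GGA14	1.00	1.00
MAM16	20	9qt	GGA17	1.00	1.00
MAM17	20	7q-17pq	GGA19	1.00	1.00
MAM18	9	19p	GGA28	0.60	1.00
MAM18	9	19p	GGA30	0.40	1.00
MAM19	6	19qt	GGA32	1.00	1.00
MAMX	54	Xpq	GGA4	1.00	0.30
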