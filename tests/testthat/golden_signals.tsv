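drug	pt	stratum	n	prr_fmt	ror_fmt	ic_fmt	signal	reason	A	B	C	D	N	prr	prr_low	prr_high	ror	ror_low	ror_high	ror_corrected	ic	ic_low	ic_high	E
alpha	P1	all	20	0.74 (0.46–1.19)	0.62 (0.29–1.31)	-0.21 (-0.97–0.31)	FALSE	prr_below_threshold	20	45	23	32	120	0.7357859531772576	0.45540728767959643	1.1887841576963436	0.6183574879227053	0.2916976960617951	1.3108296295527675	FALSE	-0.21483243002360294	-0.9652281169614626	0.3098519914246923	23.291666666666668
alpha	P2	all	12	0.73 (0.37–1.43)	0.66 (0.28–1.59)	-0.22 (-1.20–0.45)	FALSE	prr_below_threshold	12	53	14	41	120	0.7252747252747254	0.36657860453247104	1.4349539788150236	0.6630727762803235	0.27718789635576496	1.586164159490551	FALSE	-0.22239242133644802	-1.2010282064986297	0.4451163801036528	14.083333333333334
alpha	P3	all	36	3.05 (1.67–5.56)	5.59 (2.41–12.96)	0.52 (-0.03–0.92)	FALSE	ic_lower_bound_below_threshold	36	29	10	45	120	3.0461538461538464	1.6690923521207133	5.559340825358227	5.586206896551724	2.4071704354069148	12.963646874388	FALSE	0.5221216271509247	-0.033167912900362695	0.9171050402866302	24.916666666666668
alpha	P4	all	20	0.71 (0.44–1.13)	0.57 (0.27–1.21)	-0.25 (-1.00–0.28)	FALSE	prr_below_threshold	20	45	24	31	120	0.7051282051282052	0.4396335041518295	1.1309551728241618	0.5740740740740741	0.2713655162363663	1.2144543901331568	FALSE	-0.24731005354077729	-0.9977057404786369	0.27737436790751796	23.833333333333332
alpha	P5	all	3	0.42 (0.11–1.61)	0.40 (0.09–1.66)	-0.62 (-2.69–0.59)	FALSE	prr_below_threshold	3	62	6	49	120	0.42307692307692313	0.11093601068495233	1.6134894497744547	0.3951612903225806	0.09403052883595833	1.6606568877414676	FALSE	-0.6189098326444937	-2.68827544859498	0.5875837737030221	4.875
beta	P1	all	13	0.94 (0.55–1.58)	0.90 (0.40–2.02)	-0.06 (-1.00–0.58)	FALSE	prr_below_threshold	13	25	30	52	120	0.9350877192982456	0.5531601032822872	1.5807160306645955	0.9013333333333333	0.40220675144220497	2.0198611158682045	FALSE	-0.06444006156021162	-1.002907119391956	0.5786769984791577	13.616666666666667
beta	P2	all	7	0.80 (0.37–1.73)	0.75 (0.28–1.97)	-0.22 (-1.52–0.63)	FALSE	prr_below_threshold	7	31	19	63	120	0.7950138504155124	0.36569483440340633	1.7283455025653254	0.7487266553480475	0.284564510607439	1.9699983080533132	FALSE	-0.21964181032041316	-1.522004335943808	0.6323710569098451	8.233333333333333
beta	P3	all	14	0.94 (0.57–1.55)	0.91 (0.41–2.02)	-0.06 (-0.96–0.57)	FALSE	prr_below_threshold	14	24	32	50	120	0.944078947368421	0.5746238204276324	1.5510757249864366	0.9114583333333334	0.41177264380680684	2.0175121050356792	FALSE	-0.055307371679097064	-0.9581522927904306	0.56590788998828	14.566666666666666
beta	P4	all	16	1.23 (0.76–1.99)	1.40 (0.64–3.09)	0.19 (-0.65–0.78)	FALSE	prr_below_threshold	16	22	28	54	120	1.2330827067669172	0.7638418838171172	1.9905860020785024	1.4025974025974026	0.6369812810547355	3.088441579500565	FALSE	0.19306150024024704	-0.6491827016728842	0.7764405665786603	13.933333333333334
beta	P5	all	2	0.62 (0.13–2.83)	0.60 (0.12–3.01)	-0.42 (-3.02–0.97)	FALSE	below_min_count	2	36	7	75	120	0.6165413533834586	0.13434714801381445	2.82941056845375	0.5952380952380952	0.11768304721612906	3.010700337933771	FALSE	-0.42223300068304787	-3.0153006820211186	0.969169169791039	2.85
delta	P1	all	25	1.39 (0.85–2.26)	1.67 (0.78–3.54)	0.21 (-0.46–0.68)	FALSE	prr_below_threshold	25	35	18	42	120	1.388888888888889	0.8517980322817493	2.264635832172189	1.6666666666666667	0.7842403983096892	3.5419978156759786	FALSE	0.21299372333419844	-0.45603538119474657	0.6843816124219171	21.5
delta	P2	all	16	1.60 (0.79–3.24)	1.82 (0.75–4.42)	0.29 (-0.55–0.87)	FALSE	prr_below_threshold	16	44	10	50	120	1.6	0.7910328729032718	3.2362751128208034	1.8181818181818181	0.7482018168564845	4.418306731539303	FALSE	0.289506617194985	-0.5527375847181463	0.8728856835333982	13
delta	P3	all	16	0.53 (0.33–0.87)	0.36 (0.17–0.78)	-0.51 (-1.35–0.07)	FALSE	prr_below_threshold	16	44	30	30	120	0.5333333333333333	0.32673407689835526	0.8705686506428687	0.36363636363636365	0.1694016184375749	0.7805793485226086	FALSE	-0.5101947323191839	-1.3524389342323153	0.07318433401922943	23
delta	P4	all	16	0.57 (0.35–0.94)	0.42 (0.19–0.89)	-0.45 (-1.29–0.14)	FALSE	prr_below_threshold	16	44	28	32	120	0.5714285714285714	0.34685034092475986	0.9414164373438809	0.4155844155844156	0.1934570888080894	0.8927582211679512	FALSE	-0.4474589769712214	-1.2897031788843527	0.13592008936719194	22
delta	P5	all	5	1.25 (0.35–4.43)	1.27 (0.32–4.99)	0.14 (-1.42–1.12)	FALSE	prr_below_threshold	5	55	4	56	120	1.25	0.35273754102030136	4.429639089393301	1.2727272727272727	0.32456117620595604	4.990845577032006	FALSE	0.13750352374993502	-1.4246762706375378	1.1221031956467542	4.5
gamma	P1	all	9	1.12 (0.63–1.99)	1.19 (0.47–3.04)	0.12 (-1.02–0.88)	FALSE	prr_below_threshold	9	14	34	63	120	1.1163682864450128	0.62678223517671106	1.9883750384673975	1.1911764705882353	0.46739274234832595	3.035779667767293	FALSE	0.12001914647483641	-1.0189459892537804	0.8816060288361006	8.241666666666667
gamma	P2	all	2	0.35 (0.09–1.38)	0.29 (0.06–1.33)	-1.13 (-3.73–0.26)	FALSE	below_min_count	2	21	24	73	120	0.3514492753623188	0.08939259361199185	1.3817318433428862	0.2896825396825397	0.06323166016149806	1.3271195724198757	FALSE	-1.1331250832393607	-3.7261927645774318	0.25827708723472614	4.983333333333333
gamma	P3	all	13	1.66 (1.06–2.61)	2.52 (1.00–6.36)	0.54 (-0.40–1.18)	FALSE	prr_below_threshold	13	10	33	64	120	1.6613965744400525	1.0560859792176949	2.613649486764148	2.521212121212121	0.9994805989870584	6.35981385390476	FALSE	0.535073624928797	-0.4033934329029474	1.1781906849681663	8.816666666666666
gamma	P4	all	11	1.41 (0.85–2.34)	1.78 (0.71–4.46)	0.36 (-0.66–1.06)	FALSE	prr_below_threshold	11	12	33	64	120	1.4057971014492754	0.8450716133870847	2.338577534893432	1.7777777777777777	0.708706772366576	4.459522542174523	FALSE	0.364363361207759	-0.6600377080771351	1.059263711085622	8.433333333333334
gamma	P5	all	1	0.53 (0.07–4.01)	0.51 (0.06–4.26)	-0.57 (-4.35–1.12)	FALSE	below_min_count	1	22	8	89	120	0.5271739130434783	0.06933448301175157	4.008284514740943	0.5056818181818182	0.06005603938128059	4.2579248294448035	FALSE	-0.5688428353578793	-4.35194366032301	1.1185834318927543	1.725
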