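# eimsim isotope and element reference table, version 1.
# Columns: symbol, atomic_number, covalent_radius (Angstrom, Cordero et al. 2008;
# Fe low-spin value), mass_number, exact_mass (u, CIAAW/AME2012), abundance
# (mole fraction, IUPAC 2013 representative values), source tag per row.
# Abundances for each element sum to 1 within 1e-6.
symbol	atomic_number	covalent_radius	mass_number	exact_mass	abundance	source
H	1	0.31	1	1.0078250319	0.999885	CIAAW2013
H	1	0.31	2	2.0141017781	0.000115	CIAAW2013
B	5	0.84	10	10.0129369	0.199	CIAAW2013
B	5	0.84	11	11.0093054	0.801	CIAAW2013
C	6	0.76	12	12.0000000	0.9893	CIAAW2013
C	6	0.76	13	13.0033548	0.0107	CIAAW2013
N	7	0.71	14	14.0030740	0.99636	CIAAW2013
N	7	0.71	15	15.0001089	0.00364	CIAAW2013
O	8	0.66	16	15.9949146	0.99757	CIAAW2013
O	8	0.66	17	16.9991317	0.00038	CIAAW2013
O	8	0.66	18	17.9991610	0.00205	CIAAW2013
F	9	0.57	19	18.9984032	1.0	CIAAW2013
Al	13	1.21	27	26.9815385	1.0	CIAAW2013
Si	14	1.11	28	27.9769265	0.92223	CIAAW2013
Si	14	1.11	29	28.9764947	0.04685	CIAAW2013
Si	14	1.11	30	29.9737701	0.03092	CIAAW2013
P	15	1.07	31	30.9737620	1.0	CIAAW2013
S	16	1.05	32	31.9720712	0.9499	CIAAW2013
S	16	1.05	33	32.9714589	0.0075	CIAAW2013
S	16	1.05	34	33.9678670	0.0425	CIAAW2013
S	16	1.05	36	35.9670807	0.0001	CIAAW2013
Cl	17	1.02	35	34.9688527	0.7576	CIAAW2013
Cl	17	1.02	37	36.9659026	0.2424	CIAAW2013
Cr	24	1.39	50	49.9460442	0.04345	CIAAW2013
Cr	24	1.39	52	51.9405075	0.83789	CIAAW2013
Cr	24	1.39	53	52.9406494	0.09501	CIAAW2013
Cr	24	1.39	54	53.9388804	0.02365	CIAAW2013
Fe	26	1.32	54	53.9396090	0.05845	CIAAW2013
Fe	26	1.32	56	55.9349363	0.91754	CIAAW2013
Fe	26	1.32	57	56.9353928	0.02119	CIAAW2013
Fe	26	1.32	58	57.9332744	0.00282	CIAAW2013
Ni	28	1.24	58	57.9353429	0.68077	CIAAW2013
Ni	28	1.24	60	59.9307864	0.26223	CIAAW2013
Ni	28	1.24	61	60.9310560	0.01140	CIAAW2013
Ni	28	1.24	62	61.9283451	0.03635	CIAAW2013
Ni	28	1.24	64	63.9279660	0.00925	CIAAW2013
Cu	29	1.32	63	62.9295975	0.6915	CIAAW2013
Cu	29	1.32	65	64.9277895	0.3085	CIAAW2013
Ge	32	1.20	70	69.9242474	0.2057	CIAAW2013
Ge	32	1.20	72	71.9220758	0.2745	CIAAW2013
Ge	32	1.20	73	72.9234589	0.0775	CIAAW2013
Ge	32	1.20	74	73.9211778	0.3650	CIAAW2013
Ge	32	1.20	76	75.9214026	0.0773	CIAAW2013
As	33	1.19	75	74.9215965	1.0	CIAAW2013
Se	34	1.20	74	73.9224764	0.0089	CIAAW2013
Se	34	1.20	76	75.9192136	0.0937	CIAAW2013
Se	34	1.20	77	76.9199140	0.0763	CIAAW2013
Se	34	1.20	78	77.9173091	0.2377	CIAAW2013
Se	34	1.20	80	79.9165213	0.4961	CIAAW2013
Se	34	1.20	82	81.9166994	0.0873	CIAAW2013
Sn	50	1.39	112	111.9048180	0.0097	CIAAW2013
Sn	50	1.39	114	113.9027790	0.0066	CIAAW2013
Sn	50	1.39	115	114.9033420	0.0034	CIAAW2013
Sn	50	1.39	116	115.9017410	0.1454	CIAAW2013
Sn	50	1.39	117	116.9029520	0.0768	CIAAW2013
Sn	50	1.39	118	117.9016030	0.2422	CIAAW2013
Sn	50	1.39	119	118.9033080	0.0859	CIAAW2013
Sn	50	1.39	120	119.9021947	0.3258	CIAAW2013
Sn	50	1.39	122	121.9034390	0.0463	CIAAW2013
Sn	50	1.39	124	123.9052739	0.0579	CIAAW2013
Sb	51	1.39	121	120.9038157	0.5721	CIAAW2013
Sb	51	1.39	123	122.9042140	0.4279	CIAAW2013
Te	52	1.38	120	119.9040200	0.0009	CIAAW2013
Te	52	1.38	122	121.9030439	0.0255	CIAAW2013
Te	52	1.38	123	122.9042700	0.0089	CIAAW2013
Te	52	1.38	124	123.9028179	0.0474	CIAAW2013
Te	52	1.38	125	124.9044307	0.0707	CIAAW2013
Te	52	1.38	126	125.9033117	0.1884	CIAAW2013
Te	52	1.38	128	127.9044631	0.3174	CIAAW2013
Te	52	1.38	130	129.9062244	0.3408	CIAAW2013
I	53	1.39	127	126.9044730	1.0	CIAAW2013
Pb	82	1.46	204	203.9730436	0.014	CIAAW2013
Pb	82	1.46	206	205.9744653	0.241	CIAAW2013
Pb	82	1.46	207	206.9758969	0.221	CIAAW2013
Pb	82	1.46	208	207.9766521	0.524	CIAAW2013
Bi	83	1.48	209	208.9803987	1.0	CIAAW2013
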