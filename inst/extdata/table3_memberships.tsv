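station	typ	FKM_A	FKM_B	FKM_C
ChioL1	C	0.13	0.39	0.48
ChioS1	A	0.61	0.25	0.14
ChioS3	A	0.49	0.30	0.21
ChioL2	B	0.24	0.32	0.44
ChioS2	A	0.41	0.35	0.24
ChioL3	C	0.20	0.33	0.46
TR12-Nicola	B	0.19	0.49	0.32
TR13	B	0.19	0.54	0.28
TR14-Misto	B	0.19	0.52	0.29
TR3-Spari	B	0.23	0.49	0.29
TR4	B	0.30	0.47	0.22
SanPietro	B	0.22	0.60	0.17
Menegh	A	0.70	0.19	0.11
Meneghel	A	0.70	0.19	0.11
Strucolo	C	0.10	0.21	0.69
Gubana	C	0.08	0.15	0.77
Colomba	C	0.07	0.14	0.78
Colomba2	C	0.11	0.20	0.69
Cerniotta	C	0.09	0.17	0.74
Lastre	B	0.18	0.32	0.51
Pivetta	C	0.16	0.29	0.55
Tartaruga	C	0.15	0.26	0.59
Amerigo	A	0.54	0.32	0.14
Corvine	A	0.37	0.50	0.13
NordAlti	A	0.40	0.44	0.16
Palo Largo	A	0.66	0.22	0.12
TR2-Pinnacoli	A	0.27	0.51	0.22
Salient	A	0.63	0.26	0.11
Saratoga	A	0.52	0.35	0.13
Dorsale	B	0.37	0.42	0.21
Aldebaran	B	0.25	0.55	0.20
La Longa	B	0.34	0.44	0.22
Bardelli	B	0.16	0.51	0.32
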