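level	category	pan	softcore	core	softcore_to_pan	core_to_pan
brite	Orthologs and modules	2846	1625	1419	1.8	2.0
brite	Protein families: metabolism	1342	798	698	1.7	1.9
brite	Protein families: genetic information processing	516	399	372	1.3	1.4
brite	Protein families: signaling and cellular processing	539	228	190	2.4	2.8
brite	Total	5243	3050	2679	1.7	2.0
pathway	Metabolism	2958	1850	1666	1.6	1.8
pathway	Genetic Information Processing	198	180	167	1.1	1.2
pathway	Environmental Information Processing	278	98	79	2.8	3.5
pathway	Cellular Processes	156	102	78	1.5	2.0
pathway	Organismal Systems	61	30	27	2.0	2.3
pathway	Human Diseases	88	49	47	1.8	1.9
pathway	Total	3739	2309	2064	1.6	1.8
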