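species	n_genomes	n_core	n_shell	n_cloud	n_pan
all	32	940	5304	8496	14913
G_stearothermophilus	8	1994	1925	1980	5899
G_thermocatenulatus	8	2142	2333	2640	7115
G_thermodenitrificans	8	2861	1101	1229	5191
P_thermoglucosidasius	8	2659	1737	2352	6748
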