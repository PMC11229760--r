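rank	cluster	taxon	mean_pc	mean_pcmet
phylum	1	Tenericutes	-0.288	0.257
phylum	1	Bacteroidetes	-0.104	0.093
phylum	1	Nitrospinae	-0.171	0.152
family	1	Anaeroplasmataceae	-0.263	0.235
family	1	Sutterellaceae	-0.207	0.185
family	1	Methanomassiliicoccaceae	NA	0.193
family	1	Pasteurellaceae	-0.205	0.183
family	1	Porphyromonadaceae	-0.171	0.153
family	1	Lactobacillaceae	-0.064	0.058
family	1	Oscillospiraceae	-0.206	0.184
family	1	Bacteroidaceae	-0.097	0.087
family	1	Enterococcaceae	0.013	-0.011
family	1	Fusobacteriaceae	-0.173	0.155
family	1	Morganellaceae	-0.057	0.051
family	1	Xanthomonadaceae	-0.140	0.125
genus	1	Provencibacterium	0.309	-0.275
genus	1	Porphyromonas	0.302	-0.270
genus	1	Raoultella	0.224	-0.200
genus	1	Pseudoramibacter	0.203	-0.181
genus	1	Kluyvera	0.203	-0.182
genus	1	Slackia	0.248	-0.221
genus	1	Leptotrichia	0.202	-0.180
species	2	Eubacterium ventriosum	0.213	-0.190
species	2	Raoultella ornithinolytica	0.305	-0.272
species	2	Bacteroides sp. Marseille-P3108	0.065	-0.058
species	2	Clostridium disporicum	NA	0.168
species	2	Veillonella sp. 2011 Oral VSA C3	0.154	-0.137
species	2	Bacteroides eggerthii	0.254	-0.227
species	2	Prevotella oris	0.117	-0.104
species	2	Prevotella sp. 109	0.169	-0.151
species	2	Bifidobacterium boum	-0.154	0.137
species	2	Romboutsia sedimentorum	-0.167	0.149
species	2	Parabacteroides distasonis	0.154	-0.137
species	2	Prevotella multisaccharivorax	0.100	-0.090
species	2	Desulfovibrio legallii	0.085	-0.076
species	2	Eikenella corrodens	-0.023	0.020
species	2	Clostridium sp. 14505	0.301	-0.269
species	2	Unknown	0.110	-0.098
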