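ID	Pathway	p	p.adjust	Count	GeneIDs
hsa05034	Alcoholism	1.95e-11	2.84e-09	12	MAOB/MAOA/HDAC5/CREB1/GRIN2D/GRIN1/HDAC2/HDAC9/GRIN2B/GRIN2A/CALM1/HDAC6
hsa05031	Amphetamine addiction	6.17e-10	4.51e-08	8	MAOB/MAOA/CREB1/GRIN2D/GRIN1/GRIN2/GRIN2A/CALM1
hsa04015	Rap1 signaling pathway	4.29e-06	8.94e-05	8	EGFR/GRIN1/PDGFRB/KIT/GRIN2B/GRIN2A/CSF1R/CALM1
hsa04014	Ras signaling pathway	8.96e-06	1.45e-04	8	EGFR/GRIN1/PDGFRB/KIT/GRIN2B/GRIN2A/CSF1R/CALM1
hsa05030	Cocaine addiction	2.00e-09	9.73e-08	7	MAOB/MAOA/CREB1/GRIN2D/GRIN1/GRIN2B/GRIN2A
hsa00982	Drug metabolism - cytochrome P450	3.18e-08	1.16e-06	7	MAOB/CYP2D6/MAOA/ALDH3A1/CYP2B6/CYP2C9/CYP2E1
hsa00980	Metabolism of xenobiotics by cytochrome P450	1.18e-06	3.44e-05	6	CYP2D6/ALDH3A1/CYP2B6/CYP2C9/CYP2E1/HSD11B1
hsa04713	Circadian entrainment	4.97e-06	9.06e-05	6	CREB1/GRIN2D/GRIN1/GRIN2B/GRIN2A/CALM1
hsa04720	Long-term potentiation	1.32e-05	1.93e-04	5	GRIN2D/GRIN1/GRIN2B/GRIN2A/CALM1
hsa00340	Histidine metabolism	3.36e-06	8.18e-05	4	MAOB/MAOA/ALDH2/ALDH3A1
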