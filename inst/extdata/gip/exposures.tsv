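gene_label	genes	drugs	col_a_pct	actionable_label	exposures	risky_printed	share_printed
CYP3A5	CYP3A5	Tacrolimus	11.85	N+I	261514	30983	0.25
CYP2B6	CYP2B6	Efavirenz	43.98	I+P	27154	11941	0.10
CYP2C9	CYP2C9	Phenytoin	35.1	I+P	50133	17597	0.14
CYP2C19	CYP2C19	Citalopram;Clopidogrel;Escitalopram;Esomeprazole;Imipramine;Lansoprazole;Omeprazole;Pantoprazole;Sertraline;Voriconazole	9.88	I+P+U	15471291	1528438	12.35
CYP2D6	CYP2D6	Amitriptyline;Aripiprazole;Clomipramine;Codeine;Doxepin;Flecainide;Haloperidol;Imipramine;Metoprolol;Nortriptyline;Oxycodone;Paroxetine;Pimozide;Propafenone;Tamoxifen;Tramadol;Venlafaxine;Zuclopenthixol	40.1	I+P+U	18638754	7467420	60.31
DPYD	DPYD	Capecitabine;Fluorouracil;Tegafur	7.00	I+P	275923	19301	0.16
FVL	FVL	Contraceptives with Estrogen	3.6	Het+Hom	2561819	92226	0.74
HLA (carbamazepine)	HLA-A*31:01;HLA-B*15:02	Carbamazepine	38.54	Het+Hom	245493	96063	0.16
HLA-B*57:01	HLA-B*57:01	Abacavir;Flucloxacillin	6.4	Het+Hom	1729046	110659	0.89
HLA-B*5801	HLA-B*5801	Allopurinol	12.45	Het+Hom	692108	86168	0.70
SLCO1B1	SLCO1B1	Atorvastatin;Simvastatin	29.52	I+P	9226089	2723364	22.00
TPMT	TPMT	6-Mercaptopurine;Azathioprine;Thioguanine	20.5	I+P	193641	39696	0.32
VKORC1	VKORC1	Acenocoumarol;Phenprocoumon	12.05	P	1931864	232755	1.88
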