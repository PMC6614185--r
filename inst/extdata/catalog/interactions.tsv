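drug	gene	actionable_set	therapeutic_area
Tacrolimus	CYP3A5	N+I	other
Efavirenz	CYP2B6	I+P	infectious
Phenytoin	CYP2C9	I+P	psychiatry/neurology
Citalopram;Clopidogrel;Escitalopram;Esomeprazole;Imipramine;Lansoprazole;Omeprazole;Pantoprazole;Sertraline;Voriconazole	CYP2C19	I+P+U	mixed
Amitriptyline;Aripiprazole;Clomipramine;Codeine;Doxepin;Flecainide;Haloperidol;Imipramine;Metoprolol;Nortriptyline;Oxycodone;Paroxetine;Pimozide;Propafenone;Tamoxifen;Tramadol;Venlafaxine;Zuclopenthixol	CYP2D6	I+P+U	mixed
Capecitabine;Fluorouracil;Tegafur	DPYD	I+P	oncology
Contraceptives with Estrogen	FVL	Het+Hom	endocrinology
Carbamazepine	HLA-A*31:01;HLA-B*15:02	Het+Hom	psychiatry/neurology
Abacavir;Flucloxacillin	HLA-B*57:01	Het+Hom	infectious
Allopurinol	HLA-B*5801	Het+Hom	other
Atorvastatin;Simvastatin	SLCO1B1	I+P	cardiovascular
6-Mercaptopurine;Azathioprine;Thioguanine	TPMT	I+P	oncology
Acenocoumarol;Phenprocoumon	VKORC1	P	cardiovascular
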