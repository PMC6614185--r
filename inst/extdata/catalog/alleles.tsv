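gene	category	star_name	rsids	risk_alleles	function	maf
CYP3A5	enzyme	*1	rs776746	A	normal	0.06
CYP3A5	enzyme	*6	rs10264272	A	inactive	0.00
CYP3A5	enzyme	*7	rs41303343	del	inactive	0.00
CYP3A5	enzyme	*3	-	-	inactive
CYP2B6	enzyme	*6	rs3745274	T	decreased	0.25
CYP2B6	enzyme	*1	-	-	normal
CYP2C9	enzyme	*2	rs1799853	T	decreased	0.13
CYP2C9	enzyme	*3	rs1057910	C	decreased	0.07
CYP2C9	enzyme	*1	-	-	normal
CYP2C19	enzyme	*2	rs4244285	A	inactive	0.14
CYP2C19	enzyme	*3	rs4986893	A	inactive	0.00
CYP2C19	enzyme	*17	rs12248560	T	increased	0.23
CYP2C19	enzyme	*1	-	-	normal
CYP2D6	enzyme	*2	rs16947	T	normal	0.32
CYP2D6	enzyme	*4	rs3892097;rs1065852	A;T	inactive	0.21
CYP2D6	enzyme	*10	rs1065852	T	decreased	0.02
CYP2D6	enzyme	*17	rs28371706	T	decreased	0.00
CYP2D6	enzyme	*41	rs28371725	A	decreased	0.09
CYP2D6	enzyme	*42	rs72549346	ins	inactive	0.00
CYP2D6	enzyme	*1	-	-	normal
DPYD	enzyme	*2A	rs3918290	A	inactive	0.007
DPYD	enzyme	*13	rs55886062	G	inactive	0.002
DPYD	enzyme	c.1236G>A	rs56038477	A	decreased	0.021
DPYD	enzyme	c.2846A>T	rs67376798	T	decreased	0.006
DPYD	enzyme	*1	-	-	normal
FVL	carrier	Leiden	rs6025	A	risk-tag	0.018
FVL	carrier	non-carrier	-	-	non-carrier
HLA-A*31:01	carrier	A*31:01	rs1061235	T	risk-tag	0.022
HLA-A*31:01	carrier	non-carrier	-	-	non-carrier
HLA-B*15:02	carrier	B*15:02	rs3909184;rs2844682	C;A	risk-tag	0.006
HLA-B*15:02	carrier	non-carrier	-	-	non-carrier
HLA-B*57:01	carrier	B*57:01	rs2395029	G	risk-tag	0.032
HLA-B*57:01	carrier	non-carrier	-	-	non-carrier
HLA-B*5801	carrier	B*58:01	rs3134792;rs4713518	G;G	risk-tag	0.0631
HLA-B*5801	carrier	non-carrier	-	-	non-carrier
SLCO1B1	transporter	*5	rs4149056	C	decreased	0.163
SLCO1B1	transporter	*1	-	-	normal
TPMT	enzyme	*2	rs1800462	C	inactive	0.001
TPMT	enzyme	*3A	rs1800460;rs1142345	A;G	inactive	0.021
TPMT	enzyme	*3B	rs1800460	A	inactive	0.017
TPMT	enzyme	*3C	rs1142345	G	inactive	0.063
TPMT	enzyme	*1	-	-	normal
VKORC1	sensitivity	*2	rs9923231	A	increased	0.373
VKORC1	sensitivity	*1	-	-	normal
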