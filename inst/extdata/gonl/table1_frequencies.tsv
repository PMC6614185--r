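gene	star_name	change_label	rsids	activity	maf_gonl	maf_other	p_printed
CYP3A5	*1	6986A > G	rs776746	Increased	0.06	0.008	NA
CYP3A5	*6	14690G > A	rs10264272	Inactive	0.00	0.001	NA
CYP3A5	*7	Deletion	rs41303343	Inactive	0.00	0.00	NA
CYP2B6	*6	516G > T	rs3745274	Decreased or Inactive	0.25	0.30	NA
CYP2C9	*2	430C > T	rs1799853	Decreased	0.13	0.11	0.29
CYP2C9	*3	1075A > C	rs1057910	Decreased or Inactive	0.07	0.20	0.0001
CYP2C19	*2	19154G > A	rs4244285	Inactive	0.14	0.14	0.94
CYP2C19	*3	17948G > A	rs4986893	Inactive	0.00	0.00	1.00
CYP2C19	*17	-806C > T	rs12248560	Increased	0.23	0.20	0.15
CYP2D6	*2	2850C > T	rs16947	Normal	0.32	0.34	0.43
CYP2D6	*4	1846G > A	rs3892097	Inactive	0.21	0.20	0.50
CYP2D6	*10	100C > T	rs1065852	Decreased	0.23	0.21	0.29
CYP2D6	*17	1023C > T	rs28371706	Decreased	0.00	0.00	1.00
CYP2D6	*41	2988G > A	rs28371725	Decreased	0.09	0.10	0.74
CYP2D6	*42	3259insGT	rs72549346	Inactive	0.00	0.00	1.00
DPYD	*2A	1905+1G > A	rs3918290	Inactive	0.007	0.01	0.59
DPYD	*13	1679T > G	rs55886062	Inactive	0.002	0.00	1.00
DPYD	c.1236G>A	1236G > A	rs56038477	Decreased	0.021	0.25	NA
DPYD	c.2846A>T	2846 A > T	rs67376798	Decreased	0.006	0.007	NA
FVL	Leiden	1691G > A	rs6025	Decreased	0.018	0.03	NA
HLA-A*31:01	A*31:01	29913298A > T	rs1061235	Idiosyncratic reactions	0.022	0.03	NA
HLA-B*15:02	B*15:02	30699384G > C and 30946148G > A	rs3909184;rs2844682	NA	0.006	0.00	NA
HLA-B*57:01	B*57:01	31431780T > G	rs2395029	NA	0.032	0.034	NA
HLA-B*5801	B*58:01	31312326T > G and 32257337A > G	rs3134792;rs4713518	NA	0.0631	0.06	NA
SLCO1B1	*5	521T > C	rs4149056	Decreased	0.163	0.14	0.24
TPMT	*2	238G > C	rs1800462	Inactive	0.001	0.00	1.00
TPMT	*3A	460G > A and 719A > G	rs1800460;rs1142345	Inactive	0.021	0.025	NA
TPMT	*3B	460G > A	rs1800460	Inactive	0.038	0.04	0.94
TPMT	*3C	719A > G	rs1142345	Inactive	0.084	0.07	0.19
VKORC1	*2	-1639G > A	rs9923231	Increased sensitivity	0.373	0.37	0.14
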