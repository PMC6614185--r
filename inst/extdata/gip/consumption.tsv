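drug	therapeutic_area	year	items_thousands	users
6-Mercaptopurine	oncology	2011-2017	136	NA
Abacavir	infectious	2011-2017	116	NA
Acenocoumarol	cardiovascular	2011-2017	9149	NA
Allopurinol	other	2011-2017	6210	NA
Aripiprazole	psychiatry/neurology	2011-2017	1625	NA
Azathioprine	oncology	2011-2017	1093	NA
Capecitabine	oncology	2011-2017	297	NA
Carbamazepine	psychiatry/neurology	2011-2017	3033	NA
Clopidogrel	cardiovascular	2011-2017	10195	NA
Contraceptives with Estrogen	endocrinology	2011-2017	7842	NA
Efavirenz	infectious	2011-2017	145	NA
Flecainide	cardiovascular	2011-2017	1806	NA
Flucloxacillin	infectious	2011-2017	2459	NA
Fluorouracil	oncology	2011-2017	312	NA
Haloperidol	psychiatry/neurology	2011-2017	2678	NA
Metoprolol	cardiovascular	2011-2017	61224	NA
Proton Pump Inhibitors (PPI)	gastroenterology	2011-2017	110147	NA
Opioids	analgesic/anaesthesiology	2011-2017	28559	NA
Phenprocoumon	cardiovascular	2011-2017	1821	NA
Phenytoin	psychiatry/neurology	2011-2017	1028	NA
Pimozide	psychiatry/neurology	2011-2017	599	NA
Propafenone	cardiovascular	2011-2017	97	NA
SSRI	psychiatry/neurology	2011-2017	27424	NA
Simvastatin and Atorvastatin	cardiovascular	2011-2017	80653	NA
Tacrolimus	other	2011-2017	977	NA
Tamoxifen	oncology	2011-2017	1193	NA
Tegafur	oncology	2011-2017	0.812	NA
Thioguanine	oncology	2011-2017	53	NA
Tricyclic antidepressants	psychiatry/neurology	2011-2017	15034	NA
Venlafaxine	psychiatry/neurology	2011-2017	7698	NA
Voriconazole	infectious	2011-2017	24	NA
Zuclopenthixol	psychiatry/neurology	2011-2017	722	NA
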