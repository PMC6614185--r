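key	value
total_pgx_items_thousands	384351
total_all_items_thousands	1600241
insured_population	11400000
european_ancestry_fraction	0.85
printed_total_exposures	51304829
printed_total_risky	12380754
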