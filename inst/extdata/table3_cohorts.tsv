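variant_id	database	population	alt_count	allele_number	note
pooled	gnomAD	African	9	24940	
pooled	gnomAD	Ashkenazi Jewish	1	10350	
pooled	gnomAD	East Asian	9	19946	
pooled	gnomAD	European (Finnish)	1	24920	
pooled	gnomAD	European (Non-Finnish)	63	128828	variants pooled across unequal allele numbers; largest AN shown
pooled	gnomAD	Latino	11	35430	source table prints frequency 0.0508 which is inconsistent with 11/35,430; excluded from golden cells
pooled	gnomAD	South Asian	5	30614	
pooled	UK Biobank	All	77	1000000	printed AN 1,000,000 for ~50,000 individuals; printed figures correspond to AN 100,000
pooled	100,000 Genomes Project	All	11	127474	
pooled	deCODE	Iceland	1304	107928	source table prints homozygote cell 6840; exact reciprocal of (1304/107,928)^2 rounds to 6850
pooled	deCODE	Denmark	12	17662	
pooled	deCODE	Sweden	3	6306	
pooled	deCODE	Norway	3	5840	
pooled	deCODE	Ireland	7	2730	source table prints frequency 0.18315 and 1-in cells for the 5/2730 splice-dup count alone; pooled count is 7/2730
pooled	HGVD	Japan	3	2326	
pooled	KOVA	Korea	1	1898	
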