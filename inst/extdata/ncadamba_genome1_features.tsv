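gene	category	strand	segments	length	gc	init_codon	term_codon	intergenic
tRNA-Thr	tRNA	N	4421-4492	72	51.39			
orf309	PCG	J	7042-7092;10274-10531	309		ATG	TAA	2549
matR	PCG	J	7756-9723	1968	51.78	ATG	TAG	663
ccmFc	other	N	12975-13523;14475-15242	1317		ATG	TGA	3251
ccmFn	other	J	37088-38716	1629	45.30	ATG	TAA	21845
nad7	PCG	N	47657-47917;49703-50413;51678-51746;52647-52790	1185		ATG	TAG	8940
atp6	PCG	J	66186-67004	819	37.61	ACG	TAA	13395
rpl16	PCG	N	72277-72792	516	44.57	ATG	TAA	5272
rps3	PCG	N	72683-74287;76033-76101	1674		ATG	TAG	-110
tRNA-Tyr	tRNA	N	91413-91496	84	50.00			15311
tRNA-Asn	tRNA	N	92321-92392	72	52.78			824
tRNA-Cys	tRNA	N	94407-94478	72	51.39			2014
atp9	PCG	N	99941-100186	246	45.53	ATG	TAA	5462
tRNA-Arg	tRNA	J	104397-104467	71	43.66			4210
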