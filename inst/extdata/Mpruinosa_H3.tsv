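#genome_length=16314
#record_id=Mpruinosa_H3
#organism=Metcalfa pruinosa (haplotype H3)
#circular=true
name	ftype	strand	start	end	anticodon	start_codon	stop_codon
trnI	tRNA	major	1	65	GAT
trnQ	tRNA	minor	69	137	TTG
trnM	tRNA	major	137	202	CAT
ND2	PCG	major	203	1180		ATT	TAA
trnW	tRNA	major	1179	1246	TCA
trnC	tRNA	minor	1239	1302	GCA
trnY	tRNA	minor	1310	1373	GTA
COI	PCG	major	1374	2918		ATC	TAA
trnL2	tRNA	major	2921	2983	TAA
COII	PCG	major	2984	3661		ATA	TAA
trnK	tRNA	major	3672	3741	CTT
trnD	tRNA	major	3742	3810	GTC
ATP8	PCG	major	3811	3966		ATT	TAA
ATP6	PCG	major	3960	4611		ATG	T
COIII	PCG	major	4612	5394		ATG	TAA
trnG	tRNA	major	5401	5465	TCC
ND3	PCG	major	5467	5817		ATG	TAA
trnA	tRNA	major	5816	5883	TGC
trnR	tRNA	major	5901	5964	TCG
trnN	tRNA	major	5990	6054	GTT
trnS1	tRNA	major	6056	6116	GCT
trnE	tRNA	major	6120	6184	TTC
trnF	tRNA	minor	6197	6261	GAA
ND5	PCG	minor	6268	7950		ATG	TAA
trnH	tRNA	minor	7952	8016	GTG
ND4	PCG	minor	8031	9362		ATG	TAG
ND4L	PCG	minor	9362	9634		ATG	TAA
trnT	tRNA	major	9637	9700	TGT
trnP	tRNA	minor	9708	9773	TGG
ND6	PCG	major	9775	10275		ATA	TAA
CytB	PCG	major	10280	11404		ATG	TAA
trnS2	tRNA	major	11420	11482	TGA
ND1	PCG	minor	11492	12442		ATG	TAA
trnL1	tRNA	minor	12444	12508	TAG
lrRNA	rRNA	minor	12509	13734
trnV	tRNA	minor	13735	13807	TAC
srRNA	rRNA	minor	13808	14524
AT_rich	control	major	14525	16314
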