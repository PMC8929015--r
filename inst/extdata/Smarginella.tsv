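#genome_length=16126
#record_id=Smarginella
#organism=Salurnis marginella
#circular=true
name	ftype	strand	start	end	anticodon	start_codon	stop_codon
trnI	tRNA	major	1	62	GAT
trnQ	tRNA	minor	81	149	TTG
trnM	tRNA	major	149	214	CAT
ND2	PCG	major	215	1180		ATT	TAA
trnW	tRNA	major	1179	1243	TCA
trnC	tRNA	minor	1236	1295	GCA
trnY	tRNA	minor	1296	1356	GTA
COI	PCG	major	1362	2897		ATG	TAA
trnL2	tRNA	major	2898	2959	TAA
COII	PCG	major	2960	3640		ATA	TAA
trnK	tRNA	major	3641	3709	CTT
trnD	tRNA	major	3710	3772	GTC
ATP8	PCG	major	3773	3925		ATT	TAA
ATP6	PCG	major	3919	4570		ATG	T
COIII	PCG	major	4571	5353		ATG	TAA
trnG	tRNA	major	5355	5415	TCC
ND3	PCG	major	5451	5786		ATT	TAA
trnA	tRNA	major	5786	5848	TGC
trnR	tRNA	major	5849	5909	TCG
trnN	tRNA	major	5911	5973	GTT
trnS1	tRNA	major	5972	6031	GCT
trnE	tRNA	major	6034	6095	TTC
trnF	tRNA	minor	6094	6156	GAA
ND5	PCG	minor	6156	7835		GTG	TAA
trnH	tRNA	minor	7836	7897	GTG
ND4	PCG	minor	7898	9221		ATG	T
ND4L	PCG	minor	9223	9495		ATG	TAA
trnT	tRNA	major	9498	9558	TGT
trnP	tRNA	minor	9560	9622	TGG
ND6	PCG	major	9624	10121		ATA	TAA
CytB	PCG	major	10114	11235		ATG	TAA
trnS2	tRNA	major	11235	11295	TGA
ND1	PCG	minor	11289	12230		ATG	TAA
trnL1	tRNA	minor	12232	12293	TAG
lrRNA	rRNA	minor	12294	13497
trnV	tRNA	minor	13498	13567	TAC
srRNA	rRNA	minor	13567	14290
AT_rich	control	major	14291	16126
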