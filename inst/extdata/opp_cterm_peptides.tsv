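accession	gene	protein_name	mz	z	peptide	next_aa	next_codon	fpt
P02545	LMNA	Prelamin-A/C	696.3437	3	NSNLVGAAHEELQQ	S	TCG	4.03
P04908	HIST1H2AB	Histone H2A type 1-B/E	653.3621	3	VTIAQGGVLPNIQA	V	GTG	25.87
P07992	ERCC1	DNA excision repair protein ERCC-1	1403.6621	4	STQSLPTVDTSAQAAPQTYAEYAISQPLEGAGATCPTGSEPLAGETPNQA	L	CTG	36.1
P09972	ALDOC	Fructose-bisphosphate aldolase C	898.7755	3	GVVPLAGTDGETTTQGLDGLSE	R	CGC	8.71
P11021	HSPA5	78-kDa glucose-regulated protein	1240.9471	3	GINPDEAVAYGAAVQAGVLSGDQDTGDLVLLD	V	GTA	7.66
P11142	HSPA8	Heat shock cognate 71-kDa protein	1020.0259	4	SINPDEAVAYGAAVQAAILSGDKSENVQDLLLLD	V	GTC	13.44
P14635	CCNB1	G2/mitotic-specific cyclin-B1	1149.5383	4	LSPEPILVDTASPSPMETSGCAPAEEDLCQAFSDVILA	V	GTA	7.66
P19338	NCL	Nucleolin	859.0979	3	TLVLSNLSYSATEETLQE	V	GTA	7.66
P23193	TCEA1	Transcription elongation factor A protein 1	1145.8602	3	TGDDYIAIGADEEELGSQIEEAIYQE	I	ATA	8.08
P41208	CETN2	Centrin-2	699.3281	3	ELGENLTDEELQE	M	ATG	21.53
P49006	MARCKSL1	MARCKS-related protein	1051.4657	4	GAEASAASEEEAGPQATEPSTPSGPESGPTPASAEQNE	-	TAG	0.35
P52597	HNRNPF	Heterogeneous nuclear ribonucleoprotein F	773.051	3	ITGEAFVQFASQELAE	K	AAG	31.77
P55884	EIF3B	Eukaryotic translation initiation factor 3 subunit B	1082.2559	4	TEPAAEAEAASGPSESPSPPAAEELPGSHAEPPVPAQGE	A	GCC	25.84
P57086	SCAND1	SCAN domain-containing protein 1	903.149	3	AAASAALELPLGPAPVSVAPQAE	A	GCT	18.99
P68363	TUBA1B	Tubulin alpha-1B chain	1106.2401	3	LEFSIYPAPQVSTAVVEPYNSILTT	H	CAC	14.65
Q07021	C1QBP	Complement component 1 Q subcomponent-binding protein, mitochondrial	724.3483	4	GVDNTFADELVELSTALEHQE	Y	TAC	13.49
Q13066	GAGE2B	G antigen 2B/2C	738.932	5	QDPAAAQEGEDEGASAGQGPKPEAHSQEQGH	P	CCA	18.92
Q13765	NACA	Nascent polypeptide-associated complex subunit alpha	960.129	3	VQGEAVSNIQENTQTPTVQEE	S	AGT	14.05
Q13765	NACA	Nascent polypeptide-associated complex subunit alpha	752.6938	3	NNSNDIVNAIMELTM	-	TAA	0.44
Q14103	HNRNPD	Heterogeneous nuclear ribonucleoprotein D0	794.3727	3	EYFGGFGEVESIELPM	D	GAC	24.27
Q14318	FKBP8	Peptidyl-prolyl cis-trans isomerase FKBP8	1057.5203	3	EFLAAMEPEPAPAPAPEEWLDILG	N	AAC	18.3
Q14974	KPNB1	Importin subunit beta-1	1005.4691	3	ESTLEAIGYICQDIDPEQLQD	K	AAA	27.48
Q15942	ZYX	Zyxin	765.7106	3	EVEELEQLTQQLMQ	D	GAC	24.27
Q8NC51	SERBP1	Plasminogen activator inhibitor 1 RNA-binding protein	779.7021	3	SSASAPDVDDPEAFPALA	-	TAA	0.44
Q92804	TAF15	TATA-binding protein-associated factor 2N	969.0908	3	TDADSESDNSDNNTIFVQGLGE	G	GGT	10.83
Q99729	HNRNPAB	Heterogeneous nuclear ribonucleoprotein A/B	817.7206	3	EYFGEFGEIEAIELPM	D	GAT	24.03
Q9UEU5	GAGE2D	G antigen 2D	799.7582	5	QDPAAAQEGEDEGASAGQGPKPEADSQEQGHPQT	G	GGG	15.35
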