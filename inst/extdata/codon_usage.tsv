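codon	frequency_per_thousand
AAA	27.48
AAC	18.3
AAG	31.77
AGT	14.05
ATA	8.08
ATG	21.53
CAC	14.65
CCA	18.92
CGC	8.71
CTG	36.1
GAC	24.27
GAT	24.03
GCC	25.84
GCT	18.99
GGG	15.35
GGT	10.83
GTA	7.66
GTC	13.44
GTG	25.87
TAA	0.44
TAC	13.49
TAG	0.35
TCG	4.03
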