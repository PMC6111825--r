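# Four-subpathway breast cancer prognostic signature: per-subpathway
# univariate Cox hazard ratio (hr), risk-score coefficient (beta) and
# member gene symbols (semicolon-joined).
subpathway_id	pathway	hr	beta	genes
path04390_17	Hippo signalling pathway	2.75	1.013	YWHAZ;YWHAG;YAP1;SOX2;SERPINE1;TEAD3;BIRC5;FGF1
path04730_1	Long-term depression	2.12	0.750	LYN;PRKCA;PLA2G4B;GNAS;GNAZ;GNA12;CRHR1;GRM1;GNAQ;GNAI1
path04151_102	PI3K-Akt signalling pathway	0.40	-0.927	GH2;JAK2;IL2RG;PIK3CD;IRS1;IL7R;IGF1R;FGF10;FGF18
path00230_30	Purine metabolism	2.38	0.866	PDE1A;GMPS;ITPA;POLR3A;PDE2A;ENTPD2;RRM2;ADCY7
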