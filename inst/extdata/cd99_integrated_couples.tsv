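mir	gene	r_day0	r_day7	r_day14
hsa-miR-1305	ID1	NA	NA	-0.886
hsa-miR-202	CBFA2T3	NA	NA	0.931
hsa-miR-34a	AKT3	NA	-0.909	NA
hsa-miR-34a	ARHGAP29	NA	-0.927	NA
hsa-miR-34a	C18orf25	-0.945	-0.917	NA
hsa-miR-34a	C1orf74	0.827	0.827	NA
hsa-miR-34a	CD40	0.945	NA	NA
hsa-miR-34a	DOK6	-0.885	-0.885	NA
hsa-miR-34a	DTNA	-0.892	NA	NA
hsa-miR-34a	GALM	NA	0.815	NA
hsa-miR-34a	GRB10	NA	-0.842	NA
hsa-miR-34a	KCTD12	NA	-0.87	NA
hsa-miR-34a	KCTD21	NA	0.813	NA
hsa-miR-34a	LMAN1	-0.884	-0.88	NA
hsa-miR-34a	MEX3C	-0.938	-0.938	NA
hsa-miR-34a	NTNG1	-0.856	-0.856	NA
hsa-miR-34a	NTNG1	NA	-0.856	NA
hsa-miR-34a	PEG10	NA	-0.941	NA
hsa-miR-34a	RPRD1A	NA	-0.877	NA
hsa-miR-34a	SMAD4	-0.904	-0.904	NA
hsa-miR-34a	SOCS6	-0.982	-0.994	NA
hsa-miR-34a	TMEM164	NA	0.88	NA
hsa-miR-34a	TNFRSF9	NA	0.882	NA
hsa-miR-34a	TXNL1	NA	-0.931	NA
hsa-miR-34a	ZFYVE21	NA	-0.878	NA
hsa-miR-34a	ZNF3	NA	0.823	NA
hsa-miR-378	KIF26A	0.848	NA	NA
hsa-miR-500	NEBL	NA	NA	-0.903
hsa-miR-520e	C18orf25	NA	NA	-0.823
hsa-miR-520e	EFNB2	NA	NA	-0.813
hsa-miR-892b	BACH2	NA	0.813	NA
hsa-miR-26b	ADAMTSL1	NA	NA	-0.929
hsa-miR-26b	ADNP2	NA	NA	0.94
hsa-miR-26b	ARHGAP29	NA	NA	0.924
hsa-miR-26b	C18orf25	NA	NA	0.918
hsa-miR-26b	CDH2	NA	NA	0.968
hsa-miR-26b	CNR1	NA	NA	0.844
hsa-miR-26b	DTNA	NA	NA	0.908
hsa-miR-26b	ELAVL2	NA	NA	0.885
hsa-miR-26b	HES1	NA	NA	0.909
hsa-miR-26b	HEY2	NA	NA	0.94
hsa-miR-26b	JAM2	NA	NA	0.9
hsa-miR-26b	KIAA1468	NA	NA	0.917
hsa-miR-26b	MEX3C	NA	NA	0.99
hsa-miR-26b	NEDD4L	NA	NA	0.883
hsa-miR-26b	NTNG1	NA	NA	0.907
hsa-miR-26b	PLEKHA7	NA	NA	0.863
hsa-miR-26b	RNF138	NA	NA	0.829
hsa-miR-26b	SMAD2	NA	NA	0.816
hsa-miR-26b	SMAD4	NA	NA	0.933
hsa-miR-26b	STX6	NA	NA	-0.858
hsa-miR-26b	TECPR2	NA	NA	0.885
hsa-miR-26b	VPS4B	NA	NA	0.864
hsa-miR-342-3p	BARD1	NA	NA	0.835
hsa-miR-342-3p	C18orf25	NA	NA	0.934
hsa-miR-342-3p	EFNB2	NA	NA	0.866
hsa-miR-342-3p	IGFBP5	NA	NA	0.897
hsa-miR-342-3p	KCTD12	NA	NA	0.923
hsa-miR-342-3p	KIAA1468	NA	NA	0.834
hsa-miR-342-3p	KIFAP3	NA	NA	-0.903
hsa-miR-342-3p	LPPR4	NA	NA	0.872
hsa-miR-342-3p	MEGF6	NA	NA	0.951
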