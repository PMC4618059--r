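name	synonyms	is_pdz	n_pdz_domains	other_domains	source
AFAD	MLLT4;AF-6;AFADIN;Gm314;I-afadin;S-AFADIN	TRUE	1	DIL:1;FHA:1;RA:2	pulldown
CSKP	CASK;CAGH39;CAMGUK;CMG;DXPri1;DXRib1;FGS4;LIN-2;MICPCH;mLin-2;MRXSNA;Pals3;TNRC8	TRUE	1	GuKc:1;L27:2;S_TKc:1;SH3:1	pulldown
DLG1	DLGH1;E-dlg/SAP97;hdlg;SAP-97	TRUE	3	GuKc:1;L27:1;MAGUK_N_PEST:1;SH3:1	pulldown
GORS2	GORASP2;GOLPH2;GOLPH6;GRASP55;GRS2;p59	TRUE	1		pulldown
HTRA1	ARMD7;CARASIL;HTRA;IGFBP5-protease;L56;PRSS11;PRSSS;RSPP11;SERINE PROTEASE 11/IGF binding	TRUE	1	IB:1;KAZAL:1	pulldown
INADL	CIPP;hINADL;Inadl2;InaD-like;PATJ	TRUE	10	L27:1	pulldown
LIN7A	LIN7;lin-7 homolog A;MALS-1;Mlin-7;protein lin-7 homolog A-like;TIP-33;Veli;VELI1	TRUE	1	L27:1	pulldown
LIN7C	lin-7 homolog C;MALS-3;VELI	TRUE	1	L27:1	pulldown
LNX1	E3 ubiquitin protein ligase;LNX;MPDZ;PDZRN2	TRUE	4	RING:1	pulldown
LNX2	PDZRN1	TRUE	4	RING:1	pulldown
MAGI1	AIP-3;BAIAP1;BAP-1;Gukmi1;Magi1d;TNRC19;WWP3	TRUE	6	GuKc:1;WW:2	pulldown
MAGI3	Slipr	TRUE	6	GuKc:1;WW:2	pulldown
MPDZ	INAD;MUPP1	TRUE	13	L27:1	pulldown
MPP2	DLG2;Dlgh2;Pals4	TRUE	1	GuKc:1;L27:2;SH3:1	pulldown
MPP5	PALS1	TRUE	1	GuKc:1;L27:2;SH3:1	pulldown
MPP6	FIN15;PALS2;VAM-1	TRUE	1	GuKc:1;L27:2;SH3:1	pulldown
MPP7	Gm955	TRUE	1	GuKc:1;L27:2;SH3:1	pulldown
PTN13	FAP-1;hPTP1E;PNP1;ptp;PTP1E;PTP-BAS;PTP-BAS5E;PTP-BL;PTPL1;PTPLE;Ptpri;RIP;FRIED	TRUE	5	B41:1;FERM_C:1;KIND:1;PTPc:1	pulldown
SCRIB	CRC;CRIB;CRIB1;SCRB1;SCRIB1;Vartul	TRUE	4	LRR:11	pulldown
SDCB1	MDA-9;ST1;syntenin-1;TACIP18;MDA9;SYCL;SDCBP	TRUE	2		pulldown
SNTA1	alpha SYNTROPHIN;SNT1;syntrophin alpha1;TACIP1;a-1-syntrophin	TRUE	1	PH:1	pulldown
SNTB1	59-DAP;A1B;BSYN2;DAPA1B;SNT2;SNT2B1;TIP-43;syntrophin basic 1;syntrophin beta 1	TRUE	1	PH:1	pulldown
SNTB2	Snt2;SNT2B2;SNT3;SNTL;syntrophin basic 2;syntrophin beta 2	TRUE	1	PH:1	pulldown
SNX27	MRT1;MY014;SNTX27	TRUE	1	PX:1	pulldown
TJP1	ZO-1	TRUE	3	GuKc:1;SH3:1;ZU5:1	pulldown
TJP2	ZO-2	TRUE	3	GuKc:1;SH3:1	pulldown
NEB1	PPP1R9A;NEURABIN-1	TRUE	1		validation
NEB2	PPP1R9B;SPINOPHILIN	TRUE	1		validation
PDZD8	PDZK8	TRUE	1		validation
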