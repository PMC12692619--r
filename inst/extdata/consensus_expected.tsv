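allergen	positions	peptides	n	flag
Ses i 1	38~45, 61~70, 78~87, 116~126, 140~144	NQQSQQCR, SQGRSPYGGE, STGNQQSEQS, QEGGYQEGQSQ, NMRPQ	5	rule-consistent
Ses i 2	75~79	ANQGQ	1	rule-consistent
Ses i 3	23~29, 61~72, 81~85, 115~134, 142~151, 162~175, 188~193, 208~212, 240~244, 270~274, 312~318, 325~330, 378~394, 399~409, 441~448, 468~485, 511~515, 525~530, 563~567, 574~584	SESKDPE, QKHQGEHGRGGG, NRKSP, YQREKGRQDDDNPTDPEKQY, RRQGEGGGFS, KYREQQGREGGRGE, EQGRGR, RTQHG, AEPQT, RQDRR, PVSTPGE, AGGENP, RHEEGGIWPFGGESKGT, QQRPTHSNQYG, APHYNSKA, MSRSRGSYQGETRGRPSY, SSNQN, ANNNEK, SRSQQ, GPRQQQQGRAD	20	rule-consistent
Ses i 4	2~7, 32~37, 119~133, 142~151, 153~162	ADRDRP, QKGPST, RATGQGPLEYAKRGV, EKTKQAGEAI, STAKEGGREG	5	discrepant
Ses i 5	5~13, 103~110, 132~145	YGQQQQTRA, TGKHPPGA, EQFSQQPVAGSQTS	3	rule-consistent
Ses i 6	19~32, 41~54, 56~61, 77~92, 103~109, 117~138, 165~170, 199~212, 239~246, 260~264, 268~275, 391~396, 404~409, 455~459	AIAQTREPRLTQGQ, GAQPSLRIQSEGGT, ELWDER, IRPNGLSLPNYHPSPR, ISIMVPG, HRSQRTMERTEASEQQDRGSVR, NDGSED, VPRSGEQEQQARQT, MQSEEEER, RPDEE, QEHRGRQL, AGNNGF, TGSPMR, GGRRS	14	discrepant
Ses i 7	35~43, 56~64, 74~78, 127~141, 172~176, 186~190, 204~225, 252~257, 272~290, 303~310, 314~319, 403~408, 446~450, 466~485	LQSQQQHKL, AQEPTIRFE, DRNNQ, ETFERDTQPRQDRRR, NGGEP, GNAAN, NPQGGRQSYFGRPQTEKQQGET, KGQDDL, PGEEEEERWERDPYSGANG, NLDEPARA, NPHGGR, ASQDEG, VSRDE, STSRYSWPRSSRPMSYMPKP	14	discrepant
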