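id	protein	peptide	start	charge	printed_center	role	quant_mode	fragments
a	TDP43	FGGNPGGFGNQGGFGNSR	276	2	573.28	target	ms2	y10:993.45;y14:1351.61
b	TDP43	FTEYETQVK	152	2	864.39	target	ms2	y7:896.44;y6:767.39;y5:604.33
c	TDPS6	FGVHLISNVYGR	276	2	681.87	target	ms2	y7:808.43;y6:695.35;y8:921.51
d	EIF4A1	DQIYDIFQK	194	2	585.80	target	xic	
e	TPI1	HVFGESDELIGQK	101	2	730.37	reference	xic	
f	TPI1	VVLAYEPVWAIGTGK	161	2	802.45	reference	xic	
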