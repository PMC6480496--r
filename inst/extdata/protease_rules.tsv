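name	ec	p1	p1_prime	exceptions	notes
pepsin_ph_gt2	3.4.23.1	FLWY	.	F:P,L:P,W:P,Y:P	pepsin above pH 2; C-terminal to bulky hydrophobics, blocked before proline
thermolysin	3.4.24.27	.	AFILMV	.	N-terminal to hydrophobic residues (P1' specificity)
bromelain	3.4.22.32	AGKRY	.	K:P,R:P	stem bromelain; broad, basic and small residues at P1
chymotrypsin_a	3.4.21.1	FWY	.	F:P,Y:P,W:P,W:M	high-specificity chymotrypsin; aromatic P1, blocked before proline
chymotrypsin_c	3.4.21.2	FLMWY	.	F:P,L:P,M:P,W:P,Y:P	lower-specificity chymotrypsin; aromatic plus L/M at P1
pancreatic_elastase	3.4.21.36	AGSV	.	A:P,G:P,S:P,V:P	small uncharged P1 residues
papain	3.4.22.2	AGKR	.	A:P,G:P,K:P,R:P	broad cysteine protease; simplified P1 set
proteinase_k	3.4.21.67	AFILTVWY	.	.	broad serine protease; aliphatic and aromatic P1
trypsin	3.4.21.4	KR	.	K:P,R:P	C-terminal to K/R, poorly before proline
ficin	3.4.22.3	FY	.	F:P,Y:P	cysteine protease; aromatic P1 preference
cathepsin_g	3.4.21.20	FLMY	.	F:P,L:P,M:P,Y:P	EC 3.4.21.20 resolved to cathepsin G; chymotrypsin-like
subtilisin	3.4.21.62	AFILMVWY	.	.	broad bacterial serine protease; large uncharged P1
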