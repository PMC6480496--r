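sequence	activity	ic50_value	ic50_units	source
WV	AC	307.61	uM	Lin2018-Csorokiniana
VW	AC	0.58	uM	Lin2018-Csorokiniana
IW	AC	0.50	uM	Lin2018-Csorokiniana
LW	AC	1.11	uM	Lin2018-Csorokiniana
IVVE	AC	315.3	uM	SuetsunaChen2001-Cvulgaris
AFL	AC	63.8	uM	SuetsunaChen2001-Cvulgaris
FAL	AC	26.3	uM	SuetsunaChen2001-Cvulgaris
AEL	AC	57.1	uM	SuetsunaChen2001-Cvulgaris
VVPPA	AC	79.5	uM	SuetsunaChen2001-Cvulgaris
IAE	AC	34.7	uM	SuetsunaChen2001-Splatensis
IAPG	AC	11.4	uM	SuetsunaChen2001-Splatensis
VAF	AC	35.8	uM	SuetsunaChen2001-Splatensis
GMNNLTP	AC	123	uM	Samarakoon2013-Noculata
LEQ	AC	173	uM	Samarakoon2013-Noculata
LNGDVW	AO	.	.	Ko2012-Cellipsoidea
LDAVNR	other:anti-inflammatory	.	.	Vo2013-Smaxima
MMLDF	other:anti-inflammatory	.	.	Vo2013-Smaxima
VPL	AC	.	.	multifunctional
VPL	DPP	.	.	multifunctional
WG	AC	.	.	multifunctional
WG	DPP	.	.	multifunctional
LA	AC	.	.	multifunctional
LA	DPP	.	.	multifunctional
IR	AC	.	.	multifunctional
IR	DPP	.	.	multifunctional
PG	AC	.	.	multifunctional
PG	DPP	.	.	multifunctional
VY	AC	.	.	multifunctional
VY	DPP	.	.	multifunctional
KP	AC	.	.	multifunctional
KP	DPP	.	.	multifunctional
HLY	AO	.	.	synthetic
EW	AO	.	.	synthetic
AH	AO	.	.	synthetic
WY	AO	.	.	synthetic
GHK	AO	.	.	synthetic
PGP	AA	.	.	synthetic
GPA	AA	.	.	synthetic
APG	AA	.	.	synthetic
GGP	AA	.	.	synthetic
PAG	AA	.	.	synthetic
GPR	AT	.	.	synthetic
RGD	AT	.	.	synthetic
GGR	AT	.	.	synthetic
RPG	AT	.	.	synthetic
PRG	AT	.	.	synthetic
EE	S	.	.	synthetic
DE	S	.	.	synthetic
ED	S	.	.	synthetic
SE	S	.	.	synthetic
EEE	S	.	.	synthetic
QRP	R	.	.	synthetic
RPQ	R	.	.	synthetic
PQR	R	.	.	synthetic
QPR	R	.	.	synthetic
RQP	R	.	.	synthetic
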