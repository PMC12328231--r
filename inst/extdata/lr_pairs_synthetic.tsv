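ligand	receptor
CDO1	SLC6A6
APOE	LDLR
KITLG	KIT
THBS1	CD47
L_SURF01	SURF01
L_SURF02	SURF02
L_SURF03	SURF03
L_PRKD2	PRKD2
L_CD33	CD33
L_SURF04	SURF04
L_SURF05	SURF05
L_SURF06	SURF06
L_SURF07	SURF07
L_SURF08	SURF08
L_SURF09	SURF09
PVR_NE	CD96
L_CD274	CD274
L_CD3D	CD3D
L_LGALS3BP	LGALS3BP
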