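gene	category	name_source
SLC6A6	both	printed
LDLR	both	printed
KIT	both	printed
CD47	both	printed
MR1	both	printed
CD96	both	printed
CHST11	both	printed
ST3GAL4	both	printed
ACAA1	both	printed
CLCN6	both	printed
SURF01	both	placeholder
SURF02	both	placeholder
SURF03	both	placeholder
PRKD2	AML_only	printed
CD33	AML_only	printed
CD274	AML_only	printed
CD3D	AML_only	printed
LGALS3BP	AML_only	printed
TMCO3	AML_only	printed
CHPF2	AML_only	printed
CTSK	AML_only	printed
ATP6AP1	AML_only	printed
CTSD	AML_only	printed
PNPLA6	AML_only	printed
DMXL2	AML_only	printed
TUBB6	AML_only	printed
SURF04	AML_only	placeholder
SURF05	AML_only	placeholder
SURF06	AML_only	placeholder
SURF07	AML_only	placeholder
SURF08	AML_only	placeholder
TSPAN15	bcCML_only	printed
MAN2B2	bcCML_only	printed
CLN3	bcCML_only	printed
MGAT4B	bcCML_only	printed
MYH9	bcCML_only	printed
PIGG	bcCML_only	printed
SURF09	bcCML_only	placeholder
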