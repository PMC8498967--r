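# Superfamily dialect table: annotation-tool superfamily name -> Wicker order/class.
# Editable; names are matched case- and punctuation-insensitively.
superfamily	order	class
Copia	LTR	I
Gypsy	LTR	I
Bel-Pao	LTR	I
ERV	LTR	I
Retrovirus	LTR	I
DIRS	DIRS	I
Ngaro	DIRS	I
VIPER	DIRS	I
Penelope	PLE	I
Jockey	LINE	I
L1	LINE	I
RTE	LINE	I
R2	LINE	I
I	LINE	I
CR1	LINE	I
Rex-Babar	LINE	I
7SL	SINE	I
5S	SINE	I
tRNA	SINE	I
Tc1-Mariner	TIR	II
hAT	TIR	II
CACTA	TIR	II
piggyBac	TIR	II
PIF-Harbinger	TIR	II
Mutator	TIR	II
Merlin	TIR	II
Transib	TIR	II
P	TIR	II
Sola	TIR	II
Zisupton	TIR	II
Kolobok	TIR	II
Academ	TIR	II
Ginger	TIR	II
Helitron	Helitron	II
Maverick	Maverick	II
Crypton	Crypton	II
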