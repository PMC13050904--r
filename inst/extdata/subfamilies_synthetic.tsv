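# SYNTHETIC stand-in receptor -> subfamily map for the 23-receptor screen
# repertoire (16 subfamilies, single letters; the 9-exon clade is labelled
# "9-exon" by convention but has no member in this repertoire). V-subfamily
# membership of HsOr152/129/165/157/139 and the M/C placements of
# HsOr62/HsOr219 follow the screen; remaining letters are placeholders.
receptor	subfamily
HsOr13	G
HsOr16	G
HsOr55	I
HsOr62	M
HsOr70	A
HsOr84	J
HsOr101	K
HsOr115	B
HsOr129	V
HsOr139	V
HsOr152	V
HsOr157	V
HsOr165	V
HsOr178	N
HsOr187	F
HsOr191	H
HsOr196	D
HsOr203	O
HsOr213	L
HsOr219	C
HsOr225	A
HsOr240	E
HsOr271	B
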