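# 32-row isoform taxonomy of the 5-HT2C editing cassette.
# One row per editing code over sites A,B,E,C,D, in decreasing-abundance
# report order; pattern columns follow the AnB-nnn-ECn-nnn-Dnn display
# convention (edited site = G, unedited = A, other positions = n).
label	pattern	protein	edited_sites
ABD edited form	GnG-nnn-AAn-nnn-Gnn	VNV	ABD
AD edited form	GnA-nnn-AAn-nnn-Gnn	VNV	AD
AB edited form	GnG-nnn-AAn-nnn-Ann	VNI	AB
A edited form	GnA-nnn-AAn-nnn-Ann	VNI	A
ABCD edited form	GnG-nnn-AGn-nnn-Gnn	VSV	ABCD
ACD edited form	GnA-nnn-AGn-nnn-Gnn	VSV	ACD
UNEDITED	AnA-nnn-AAn-nnn-Ann	INI	-
ABECD edited form	GnG-nnn-GGn-nnn-Gnn	VGV	ABECD
AECD edited form	GnA-nnn-GGn-nnn-Gnn	VGV	AECD
ABC edited form	GnG-nnn-AGn-nnn-Ann	VSI	ABC
AC edited form	GnA-nnn-AGn-nnn-Ann	VSI	AC
B edited form	AnG-nnn-AAn-nnn-Ann	MNI	B
E edited form	AnA-nnn-GAn-nnn-Ann	IDI	E
C edited form	AnA-nnn-AGn-nnn-Ann	ISI	C
D edited form	AnA-nnn-AAn-nnn-Gnn	INV	D
ABED edited form	GnG-nnn-GAn-nnn-Gnn	VDV	ABED
AED edited form	GnA-nnn-GAn-nnn-Gnn	VDV	AED
ABE edited form	GnG-nnn-GAn-nnn-Ann	VDI	ABE
AE edited form	GnA-nnn-GAn-nnn-Ann	VDI	AE
CD edited form	AnA-nnn-AGn-nnn-Gnn	ISV	CD
BD edited form	AnG-nnn-AAn-nnn-Gnn	MNV	BD
ABEC edited form	GnG-nnn-GGn-nnn-Ann	VGI	ABEC
AEC edited form	GnA-nnn-GGn-nnn-Ann	VGI	AEC
ECD edited form	AnA-nnn-GGn-nnn-Gnn	IGV	ECD
BC edited form	AnG-nnn-AGn-nnn-Ann	MSI	BC
EC edited form	AnA-nnn-GGn-nnn-Ann	IGI	EC
ED edited form	AnA-nnn-GAn-nnn-Gnn	IDV	ED
BE edited form	AnG-nnn-GAn-nnn-Ann	MDI	BE
BEC edited form	AnG-nnn-GGn-nnn-Ann	MGI	BEC
BED edited form	AnG-nnn-GAn-nnn-Gnn	MDV	BED
BCD edited form	AnG-nnn-AGn-nnn-Gnn	MSV	BCD
BECD edited form	AnG-nnn-GGn-nnn-Gnn	MGV	BECD
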