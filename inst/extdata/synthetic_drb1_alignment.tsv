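allele	9	10	11	12	13	14	16	25	26	28	30	31	32	33	37	38	40	47	57	58	60	67	70	71	73	74	77	78	85	86
DRB1*01:01	W	Q	L	K	F	E	H	R	L	D	C	I	Y	H	S	V	F	Y	D	E	H	L	Q	R	A	A	T	Y	V	G
DRB1*03:01	E	Y	S	K	S	E	Y	Q	F	D	Y	F	H	N	N	A	Y	F	D	A	H	L	Q	K	G	R	N	V	A	V
DRB1*04:01	E	Y	S	K	H	E	H	R	F	D	Y	F	Y	H	Y	A	F	Y	S	E	S	L	Q	K	A	E	T	Y	V	G
DRB1*07:01	K	Q	G	K	G	E	Y	Q	Y	E	G	V	H	N	F	V	Y	F	V	A	Y	I	D	R	G	Q	N	V	A	G
DRB1*09:01	E	Y	D	K	S	E	Y	Q	F	D	Y	F	H	N	N	A	Y	F	D	A	H	L	Q	R	G	R	N	V	A	G
DRB1*10:01	K	Q	V	K	F	E	H	R	L	H	H	I	Y	H	Y	V	F	Y	A	E	Y	F	R	A	A	Q	T	Y	V	V
DRB1*11:01	E	E	D	T	S	E	Y	Q	F	E	Y	F	H	N	Y	A	Y	F	D	A	H	L	Q	R	G	R	N	V	A	V
DRB1*12:01	K	E	S	T	G	K	H	R	L	D	L	V	Y	H	L	L	F	Y	V	E	S	I	D	E	A	L	T	Y	V	V
DRB1*13:01	E	Y	D	K	S	E	Y	Q	F	D	Y	F	H	N	N	A	Y	F	D	A	H	L	Q	E	G	E	N	V	A	V
DRB1*13:02	E	Y	S	K	G	E	Y	Q	F	D	G	F	H	N	N	A	Y	F	D	A	H	L	Q	R	G	E	N	V	A	G
DRB1*14:02	E	Y	S	K	S	E	Y	Q	F	D	Y	F	H	N	N	A	Y	F	S	A	H	F	Q	R	G	R	N	V	A	G
DRB1*15:01	W	Q	P	K	R	E	H	R	Y	E	R	I	Y	H	S	V	F	Y	D	E	Y	L	Q	A	A	A	T	Y	V	V
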