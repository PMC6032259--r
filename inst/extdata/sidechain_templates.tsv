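aa	atom	element	parent	angle_ref	torsion_ref	torsion_kind	bond	angle	torsion
ALA	CB	C	CA	N	C	improper	1.522	109.1	122.5
SER	CB	C	CA	N	C	improper	1.533	111.3	121.7
SER	OG	O	CB	CA	N	CHI1	1.431	110.7	50.7
CYS	CB	C	CA	N	C	improper	1.534	113.5	121.0
CYS	SG	S	CB	CA	N	CHI1	1.825	112.5	57.4
THR	CB	C	CA	N	C	improper	1.547	113.4	124.3
THR	OG1	O	CB	CA	N	CHI1	1.429	111.8	171.7
THR	CG2	C	CB	CA	OG1	fixed	1.525	114.7	123.2
VAL	CB	C	CA	N	C	improper	1.547	110.7	122.1
VAL	CG1	C	CB	CA	N	CHI1	1.535	111.8	56.0
VAL	CG2	C	CB	CA	CG1	fixed	1.534	111.8	122.0
LEU	CB	C	CA	N	C	improper	1.536	108.3	122.9
LEU	CG	C	CB	CA	N	CHI1	1.545	115.1	167.6
LEU	CD1	C	CG	CB	CA	CHI2	1.53	112.4	-63.9
LEU	CD2	C	CG	CB	CD1	fixed	1.532	109.6	-122.0
ILE	CB	C	CA	N	C	improper	1.549	112.4	125.6
ILE	CG1	C	CB	CA	N	CHI1	1.545	113.4	62.3
ILE	CG2	C	CB	CA	CG1	fixed	1.537	112.7	-124.2
ILE	CD1	C	CG1	CB	CA	CHI2	1.522	113.9	60.4
PRO	CB	C	CA	N	C	improper	1.525	104.5	121.2
PRO	CG	C	CB	CA	N	fixed	1.525	105.4	-22.2
PRO	CD	C	CG	CB	CA	fixed	1.518	105.5	-0.6
PHE	CB	C	CA	N	C	improper	1.538	111.6	121.1
PHE	CG	C	CB	CA	N	CHI1	1.512	113.2	82.3
PHE	CD1	C	CG	CB	CA	CHI2	1.401	120.6	-80.8
PHE	CD2	C	CG	CB	CD1	fixed	1.402	120.4	179.1
PHE	CE1	C	CD1	CG	CB	fixed	1.396	120.5	179.6
PHE	CE2	C	CD2	CG	CB	fixed	1.396	120.5	-179.6
PHE	CZ	C	CE1	CD1	CG	fixed	1.393	120.1	-0.1
TYR	CB	C	CA	N	C	improper	1.537	110.0	122.9
TYR	CG	C	CB	CA	N	CHI1	1.514	112.7	155.8
TYR	CD1	C	CG	CB	CA	CHI2	1.401	120.7	97.4
TYR	CD2	C	CG	CB	CD1	fixed	1.404	120.3	-179.3
TYR	CE1	C	CD1	CG	CB	fixed	1.396	120.4	-179.3
TYR	CE2	C	CD2	CG	CB	fixed	1.397	120.6	179.4
TYR	CZ	C	CE1	CD1	CG	fixed	1.389	119.8	-0.1
TYR	OH	O	CZ	CE1	CD1	fixed	1.363	117.8	-179.9
TRP	CB	C	CA	N	C	improper	1.537	111.3	124.9
TRP	CG	C	CB	CA	N	CHI1	1.502	113.0	169.3
TRP	CD1	C	CG	CB	CA	CHI2	1.382	126.2	-74.6
TRP	CD2	C	CG	CB	CD1	fixed	1.433	127.0	-179.7
TRP	NE1	N	CD1	CG	CB	fixed	1.369	108.4	179.7
TRP	CE2	C	CD2	CG	CB	fixed	1.395	107.5	-179.7
TRP	CE3	C	CD2	CG	CE2	fixed	1.41	134.2	180.0
TRP	CZ2	C	CE2	CD2	CG	fixed	1.4	122.8	179.8
TRP	CZ3	C	CE3	CD2	CE2	fixed	1.4	119.6	0.2
TRP	CH2	C	CZ2	CE2	CD2	fixed	1.398	117.6	0.1
MET	CB	C	CA	N	C	improper	1.539	111.8	127.5
MET	CG	C	CB	CA	N	CHI1	1.533	115.2	-58.8
MET	SD	S	CG	CB	CA	CHI2	1.827	111.9	95.7
MET	CE	C	SD	CG	CB	CHI3	1.808	98.5	-174.8
ASP	CB	C	CA	N	C	improper	1.527	108.4	122.5
ASP	CG	C	CB	CA	N	CHI1	1.503	113.1	165.5
ASP	OD1	O	CG	CB	CA	CHI2	1.221	125.8	142.7
ASP	OD2	O	CG	CB	OD1	fixed	1.346	114.0	175.1
ASN	CB	C	CA	N	C	improper	1.524	109.6	121.3
ASN	CG	C	CB	CA	N	CHI1	1.508	110.8	173.5
ASN	OD1	O	CG	CB	CA	CHI2	1.225	123.0	105.0
ASN	ND2	N	CG	CB	OD1	fixed	1.362	115.6	-179.1
GLU	CB	C	CA	N	C	improper	1.537	110.1	121.7
GLU	CG	C	CB	CA	N	CHI1	1.532	114.1	173.4
GLU	CD	C	CG	CB	CA	CHI2	1.505	112.7	-68.5
GLU	OE1	O	CD	CG	CB	CHI3	1.218	127.2	-8.1
GLU	OE2	O	CD	CG	OE1	fixed	1.346	112.0	-178.8
GLN	CB	C	CA	N	C	improper	1.535	108.3	122.6
GLN	CG	C	CB	CA	N	CHI1	1.531	115.0	177.9
GLN	CD	C	CG	CB	CA	CHI2	1.513	113.7	-60.9
GLN	OE1	O	CD	CG	CB	CHI3	1.224	124.7	-16.7
GLN	NE2	N	CD	CG	OE1	fixed	1.365	114.3	-177.8
LYS	CB	C	CA	N	C	improper	1.535	110.8	122.3
LYS	CG	C	CB	CA	N	CHI1	1.535	115.6	56.8
LYS	CD	C	CG	CB	CA	CHI2	1.532	113.4	61.6
LYS	CE	C	CD	CG	CB	CHI3	1.532	113.4	179.2
LYS	NZ	N	CE	CD	CG	CHI4	1.459	113.2	-66.1
ARG	CB	C	CA	N	C	improper	1.535	111.7	121.8
ARG	CG	C	CB	CA	N	CHI1	1.535	115.1	71.9
ARG	CD	C	CG	CB	CA	CHI2	1.528	116.1	-70.9
ARG	NE	N	CD	CG	CB	CHI3	1.457	111.9	-56.6
ARG	CZ	C	NE	CD	CG	CHI4	1.353	121.8	-80.9
ARG	NH1	N	CZ	NE	CD	fixed	1.281	125.6	8.2
ARG	NH2	N	CZ	NE	NH1	fixed	1.348	111.1	179.3
HIS	CB	C	CA	N	C	improper	1.54	111.5	121.4
HIS	CG	C	CB	CA	N	CHI1	1.493	113.7	65.4
HIS	ND1	N	CG	CB	CA	CHI2	1.374	123.0	-41.3
HIS	CD2	C	CG	CB	ND1	fixed	1.378	132.5	-179.1
HIS	CE1	C	ND1	CG	CD2	fixed	1.363	107.8	-0.5
HIS	NE2	N	CD2	CG	ND1	fixed	1.371	110.9	0.4
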