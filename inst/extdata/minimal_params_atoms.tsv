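resname	atom	element	charge	lj_rmin2	lj_eps	gb_radius	gb_scale	formal_charge
GLY	N	N	-0.4	1.824	0.17	1.55	0.79	0
GLY	CA	C	0.4	1.908	0.1094	1.7	0.72	0
GLY	C	C	0.55	1.908	0.086	1.7	0.72	0
GLY	O	O	-0.55	1.6612	0.21	1.5	0.85	0
ALA	N	N	-0.4	1.824	0.17	1.55	0.79	0
ALA	CA	C	0.4	1.908	0.1094	1.7	0.72	0
ALA	C	C	0.55	1.908	0.086	1.7	0.72	0
ALA	O	O	-0.55	1.6612	0.21	1.5	0.85	0
ALA	CB	C	0	1.908	0.1094	1.7	0.72	0
SER	N	N	-0.4	1.824	0.17	1.55	0.79	0
SER	CA	C	0.4	1.908	0.1094	1.7	0.72	0
SER	C	C	0.55	1.908	0.086	1.7	0.72	0
SER	O	O	-0.55	1.6612	0.21	1.5	0.85	0
SER	CB	C	0.2	1.908	0.1094	1.7	0.72	0
SER	OG	O	-0.2	1.6612	0.21	1.5	0.85	0
THR	N	N	-0.4	1.824	0.17	1.55	0.79	0
THR	CA	C	0.4	1.908	0.1094	1.7	0.72	0
THR	C	C	0.55	1.908	0.086	1.7	0.72	0
THR	O	O	-0.55	1.6612	0.21	1.5	0.85	0
THR	CB	C	0.25	1.908	0.1094	1.7	0.72	0
THR	OG1	O	-0.3	1.6612	0.21	1.5	0.85	0
THR	CG2	C	0.05	1.908	0.1094	1.7	0.72	0
VAL	N	N	-0.4	1.824	0.17	1.55	0.79	0
VAL	CA	C	0.4	1.908	0.1094	1.7	0.72	0
VAL	C	C	0.55	1.908	0.086	1.7	0.72	0
VAL	O	O	-0.55	1.6612	0.21	1.5	0.85	0
VAL	CB	C	0	1.908	0.1094	1.7	0.72	0
VAL	CG1	C	0	1.908	0.1094	1.7	0.72	0
VAL	CG2	C	0	1.908	0.1094	1.7	0.72	0
LEU	N	N	-0.4	1.824	0.17	1.55	0.79	0
LEU	CA	C	0.4	1.908	0.1094	1.7	0.72	0
LEU	C	C	0.55	1.908	0.086	1.7	0.72	0
LEU	O	O	-0.55	1.6612	0.21	1.5	0.85	0
LEU	CB	C	0	1.908	0.1094	1.7	0.72	0
LEU	CG	C	0	1.908	0.1094	1.7	0.72	0
LEU	CD1	C	0	1.908	0.1094	1.7	0.72	0
LEU	CD2	C	0	1.908	0.1094	1.7	0.72	0
PRO	N	N	-0.25	1.824	0.17	1.55	0.79	0
PRO	CA	C	0.25	1.908	0.1094	1.7	0.72	0
PRO	C	C	0.55	1.908	0.086	1.7	0.72	0
PRO	O	O	-0.55	1.6612	0.21	1.5	0.85	0
PRO	CB	C	0	1.908	0.1094	1.7	0.72	0
PRO	CG	C	0	1.908	0.1094	1.7	0.72	0
PRO	CD	C	0	1.908	0.1094	1.7	0.72	0
LYS	N	N	-0.4	1.824	0.17	1.55	0.79	1
LYS	CA	C	0.4	1.908	0.1094	1.7	0.72	1
LYS	C	C	0.55	1.908	0.086	1.7	0.72	1
LYS	O	O	-0.55	1.6612	0.21	1.5	0.85	1
LYS	CB	C	0	1.908	0.1094	1.7	0.72	1
LYS	CG	C	0	1.908	0.1094	1.7	0.72	1
LYS	CD	C	0	1.908	0.1094	1.7	0.72	1
LYS	CE	C	0.25	1.908	0.1094	1.7	0.72	1
LYS	NZ	N	0.75	1.824	0.17	1.55	0.79	1
ARG	N	N	-0.4	1.824	0.17	1.55	0.79	1
ARG	CA	C	0.4	1.908	0.1094	1.7	0.72	1
ARG	C	C	0.55	1.908	0.086	1.7	0.72	1
ARG	O	O	-0.55	1.6612	0.21	1.5	0.85	1
ARG	CB	C	0	1.908	0.1094	1.7	0.72	1
ARG	CG	C	0	1.908	0.1094	1.7	0.72	1
ARG	CD	C	0.1	1.908	0.1094	1.7	0.72	1
ARG	NE	N	-0.4	1.824	0.17	1.55	0.79	1
ARG	CZ	C	0.8	1.908	0.086	1.7	0.72	1
ARG	NH1	N	0.25	1.824	0.17	1.55	0.79	1
ARG	NH2	N	0.25	1.824	0.17	1.55	0.79	1
ASP	N	N	-0.4	1.824	0.17	1.55	0.79	-1
ASP	CA	C	0.4	1.908	0.1094	1.7	0.72	-1
ASP	C	C	0.55	1.908	0.086	1.7	0.72	-1
ASP	O	O	-0.55	1.6612	0.21	1.5	0.85	-1
ASP	CB	C	-0.1	1.908	0.1094	1.7	0.72	-1
ASP	CG	C	0.55	1.908	0.086	1.7	0.72	-1
ASP	OD1	O	-0.725	1.6612	0.21	1.5	0.85	-1
ASP	OD2	O	-0.725	1.6612	0.21	1.5	0.85	-1
GLU	N	N	-0.4	1.824	0.17	1.55	0.79	-1
GLU	CA	C	0.4	1.908	0.1094	1.7	0.72	-1
GLU	C	C	0.55	1.908	0.086	1.7	0.72	-1
GLU	O	O	-0.55	1.6612	0.21	1.5	0.85	-1
GLU	CB	C	0	1.908	0.1094	1.7	0.72	-1
GLU	CG	C	-0.1	1.908	0.1094	1.7	0.72	-1
GLU	CD	C	0.55	1.908	0.086	1.7	0.72	-1
GLU	OE1	O	-0.725	1.6612	0.21	1.5	0.85	-1
GLU	OE2	O	-0.725	1.6612	0.21	1.5	0.85	-1
ASN	N	N	-0.4	1.824	0.17	1.55	0.79	0
ASN	CA	C	0.4	1.908	0.1094	1.7	0.72	0
ASN	C	C	0.55	1.908	0.086	1.7	0.72	0
ASN	O	O	-0.55	1.6612	0.21	1.5	0.85	0
ASN	CB	C	0	1.908	0.1094	1.7	0.72	0
ASN	CG	C	0.55	1.908	0.086	1.7	0.72	0
ASN	OD1	O	-0.55	1.6612	0.21	1.5	0.85	0
ASN	ND2	N	0	1.824	0.17	1.55	0.79	0
TRP	N	N	-0.4	1.824	0.17	1.55	0.79	0
TRP	CA	C	0.4	1.908	0.1094	1.7	0.72	0
TRP	C	C	0.55	1.908	0.086	1.7	0.72	0
TRP	O	O	-0.55	1.6612	0.21	1.5	0.85	0
TRP	CB	C	0	1.908	0.1094	1.7	0.72	0
TRP	CG	C	0	1.908	0.086	1.7	0.72	0
TRP	CD1	C	0.15	1.908	0.086	1.7	0.72	0
TRP	CD2	C	0	1.908	0.086	1.7	0.72	0
TRP	NE1	N	-0.3	1.824	0.17	1.55	0.79	0
TRP	CE2	C	0.15	1.908	0.086	1.7	0.72	0
TRP	CE3	C	0	1.908	0.086	1.7	0.72	0
TRP	CZ2	C	0	1.908	0.086	1.7	0.72	0
TRP	CZ3	C	0	1.908	0.086	1.7	0.72	0
TRP	CH2	C	0	1.908	0.086	1.7	0.72	0
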