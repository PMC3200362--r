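# Per-atom partial charges for protonation/redox states, CHARMM22-derived
# for amino-acid groups (charge-set version: contpka-1).
# Acidic protonated states follow the +0.5-per-carboxylate-oxygen
# convention; basic deprotonated states spread -1 uniformly over the
# titratable protons.  Synthetic cofactor groups (CFR, RDX) are labeled
# synthetic: they stand in for pigment charge tables that are not shipped.
# columns: resname state atom charge
resname	state	atom	charge
BB	std	N	-0.47
BB	std	HN	0.31
BB	std	CA	0.07
BB	std	HA	0.09
BB	std	C	0.51
BB	std	O	-0.51
BBGLY	std	N	-0.47
BBGLY	std	HN	0.31
BBGLY	std	CA	-0.02
BBGLY	std	HA1	0.09
BBGLY	std	HA2	0.09
BBGLY	std	C	0.51
BBGLY	std	O	-0.51
ALA	std	CB	-0.27
ALA	std	HB1	0.09
ALA	std	HB2	0.09
ALA	std	HB3	0.09
GLY	std	.	0.0
SER	std	CB	0.05
SER	std	HB1	0.09
SER	std	HB2	0.09
SER	std	OG	-0.66
SER	std	HG1	0.43
THR	std	CB	0.14
THR	std	HB	0.09
THR	std	OG1	-0.66
THR	std	HG1	0.43
THR	std	CG2	-0.27
THR	std	HG21	0.09
THR	std	HG22	0.09
THR	std	HG23	0.09
ASN	std	CB	-0.18
ASN	std	HB1	0.09
ASN	std	HB2	0.09
ASN	std	CG	0.55
ASN	std	OD1	-0.55
ASN	std	ND2	-0.62
ASN	std	HD21	0.32
ASN	std	HD22	0.30
ASP	deprot	CB	-0.28
ASP	deprot	HB1	0.09
ASP	deprot	HB2	0.09
ASP	deprot	CG	0.62
ASP	deprot	OD1	-0.76
ASP	deprot	OD2	-0.76
ASP	prot	CB	-0.28
ASP	prot	HB1	0.09
ASP	prot	HB2	0.09
ASP	prot	CG	0.62
ASP	prot	OD1	-0.26
ASP	prot	OD2	-0.26
GLU	deprot	CB	-0.18
GLU	deprot	HB1	0.09
GLU	deprot	HB2	0.09
GLU	deprot	CG	-0.28
GLU	deprot	HG1	0.09
GLU	deprot	HG2	0.09
GLU	deprot	CD	0.62
GLU	deprot	OE1	-0.76
GLU	deprot	OE2	-0.76
GLU	prot	CB	-0.18
GLU	prot	HB1	0.09
GLU	prot	HB2	0.09
GLU	prot	CG	-0.28
GLU	prot	HG1	0.09
GLU	prot	HG2	0.09
GLU	prot	CD	0.62
GLU	prot	OE1	-0.26
GLU	prot	OE2	-0.26
LYS	prot	CB	-0.18
LYS	prot	HB1	0.09
LYS	prot	HB2	0.09
LYS	prot	CG	-0.18
LYS	prot	HG1	0.09
LYS	prot	HG2	0.09
LYS	prot	CD	-0.18
LYS	prot	HD1	0.09
LYS	prot	HD2	0.09
LYS	prot	CE	0.21
LYS	prot	HE1	0.05
LYS	prot	HE2	0.05
LYS	prot	NZ	-0.30
LYS	prot	HZ1	0.33
LYS	prot	HZ2	0.33
LYS	prot	HZ3	0.33
LYS	deprot	CB	-0.18
LYS	deprot	HB1	0.09
LYS	deprot	HB2	0.09
LYS	deprot	CG	-0.18
LYS	deprot	HG1	0.09
LYS	deprot	HG2	0.09
LYS	deprot	CD	-0.18
LYS	deprot	HD1	0.09
LYS	deprot	HD2	0.09
LYS	deprot	CE	0.21
LYS	deprot	HE1	0.05
LYS	deprot	HE2	0.05
LYS	deprot	NZ	-0.30
LYS	deprot	HZ1	-0.00333333333333
LYS	deprot	HZ2	-0.00333333333333
LYS	deprot	HZ3	-0.00333333333334
ARG	prot	CB	-0.18
ARG	prot	HB1	0.09
ARG	prot	HB2	0.09
ARG	prot	CG	-0.18
ARG	prot	HG1	0.09
ARG	prot	HG2	0.09
ARG	prot	CD	0.20
ARG	prot	HD1	0.09
ARG	prot	HD2	0.09
ARG	prot	NE	-0.70
ARG	prot	HE	0.44
ARG	prot	CZ	0.64
ARG	prot	NH1	-0.80
ARG	prot	HH11	0.46
ARG	prot	HH12	0.46
ARG	prot	NH2	-0.80
ARG	prot	HH21	0.46
ARG	prot	HH22	0.46
ARG	deprot	CB	-0.18
ARG	deprot	HB1	0.09
ARG	deprot	HB2	0.09
ARG	deprot	CG	-0.18
ARG	deprot	HG1	0.09
ARG	deprot	HG2	0.09
ARG	deprot	CD	0.20
ARG	deprot	HD1	0.09
ARG	deprot	HD2	0.09
ARG	deprot	NE	-0.70
ARG	deprot	HE	0.24
ARG	deprot	CZ	0.64
ARG	deprot	NH1	-0.80
ARG	deprot	HH11	0.26
ARG	deprot	HH12	0.26
ARG	deprot	NH2	-0.80
ARG	deprot	HH21	0.26
ARG	deprot	HH22	0.26
TYR	prot	CB	-0.18
TYR	prot	HB1	0.09
TYR	prot	HB2	0.09
TYR	prot	CG	0.00
TYR	prot	CD1	-0.115
TYR	prot	HD1	0.115
TYR	prot	CD2	-0.115
TYR	prot	HD2	0.115
TYR	prot	CE1	-0.115
TYR	prot	HE1	0.115
TYR	prot	CE2	-0.115
TYR	prot	HE2	0.115
TYR	prot	CZ	0.11
TYR	prot	OH	-0.54
TYR	prot	HH	0.43
TYR	deprot	CB	-0.18
TYR	deprot	HB1	0.09
TYR	deprot	HB2	0.09
TYR	deprot	CG	0.00
TYR	deprot	CD1	-0.115
TYR	deprot	HD1	0.115
TYR	deprot	CD2	-0.115
TYR	deprot	HD2	0.115
TYR	deprot	CE1	-0.36
TYR	deprot	HE1	0.115
TYR	deprot	CE2	-0.36
TYR	deprot	HE2	0.115
TYR	deprot	CZ	0.38
TYR	deprot	OH	-0.89
TYR	deprot	HH	0.00
CYS	prot	CB	-0.11
CYS	prot	HB1	0.09
CYS	prot	HB2	0.09
CYS	prot	SG	-0.23
CYS	prot	HG1	0.16
CYS	deprot	CB	-0.20
CYS	deprot	HB1	0.09
CYS	deprot	HB2	0.09
CYS	deprot	SG	-0.98
CYS	deprot	HG1	0.00
HIS	HSD	CB	-0.09
HIS	HSD	HB1	0.09
HIS	HSD	HB2	0.09
HIS	HSD	CG	-0.05
HIS	HSD	ND1	-0.36
HIS	HSD	HD1	0.32
HIS	HSD	CE1	0.25
HIS	HSD	HE1	0.13
HIS	HSD	NE2	-0.70
HIS	HSD	HE2	0.00
HIS	HSD	CD2	0.22
HIS	HSD	HD2	0.10
HIS	HSE	CB	-0.08
HIS	HSE	HB1	0.09
HIS	HSE	HB2	0.09
HIS	HSE	CG	0.22
HIS	HSE	ND1	-0.70
HIS	HSE	HD1	0.00
HIS	HSE	CE1	0.25
HIS	HSE	HE1	0.13
HIS	HSE	NE2	-0.36
HIS	HSE	HE2	0.32
HIS	HSE	CD2	-0.05
HIS	HSE	HD2	0.09
HIS	HSP	CB	-0.05
HIS	HSP	HB1	0.09
HIS	HSP	HB2	0.09
HIS	HSP	CG	0.19
HIS	HSP	ND1	-0.51
HIS	HSP	HD1	0.44
HIS	HSP	CE1	0.32
HIS	HSP	HE1	0.18
HIS	HSP	NE2	-0.51
HIS	HSP	HE2	0.44
HIS	HSP	CD2	0.19
HIS	HSP	HD2	0.13
HOH	std	OH2	-0.834
HOH	std	H1	0.417
HOH	std	H2	0.417
CFR	neutral	.	0.0
RDX	ox	X1	0.00
RDX	red	X1	-1.00
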