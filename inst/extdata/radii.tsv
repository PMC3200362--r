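# PARSE-style atomic radii (Angstrom) by element, used for the dielectric
# boundary and charge-burial model.  radius-set version: parse-1.
element	radius
H	1.00
C	1.70
N	1.50
O	1.40
S	1.85
P	1.86
FE	1.30
MG	1.18
X	1.60
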