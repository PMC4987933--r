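# Pharmacophore typing table, version v1.
# residue "*" rows are backbone defaults applied to every amino acid;
# residue-specific rows override them (e.g. proline N has no amide H).
# classes: HYDROPHOBIC POSITIVE NEGATIVE H_ACCEPTOR H_DONOR AROMATIC SULFUR NEUTRAL
residue	atom	classes
*	N	H_DONOR
*	CA	HYDROPHOBIC
*	C	NEUTRAL
*	O	H_ACCEPTOR
*	OXT	NEGATIVE,H_ACCEPTOR
ALA	CB	HYDROPHOBIC
ARG	CB	HYDROPHOBIC
ARG	CG	HYDROPHOBIC
ARG	CD	HYDROPHOBIC
ARG	NE	POSITIVE,H_DONOR
ARG	CZ	POSITIVE
ARG	NH1	POSITIVE,H_DONOR
ARG	NH2	POSITIVE,H_DONOR
ASN	CB	HYDROPHOBIC
ASN	CG	NEUTRAL
ASN	OD1	H_ACCEPTOR
ASN	ND2	H_DONOR
ASP	CB	HYDROPHOBIC
ASP	CG	NEUTRAL
ASP	OD1	NEGATIVE,H_ACCEPTOR
ASP	OD2	NEGATIVE,H_ACCEPTOR
CYS	CB	HYDROPHOBIC
CYS	SG	SULFUR
GLN	CB	HYDROPHOBIC
GLN	CG	HYDROPHOBIC
GLN	CD	NEUTRAL
GLN	OE1	H_ACCEPTOR
GLN	NE2	H_DONOR
GLU	CB	HYDROPHOBIC
GLU	CG	HYDROPHOBIC
GLU	CD	NEUTRAL
GLU	OE1	NEGATIVE,H_ACCEPTOR
GLU	OE2	NEGATIVE,H_ACCEPTOR
HIS	CB	HYDROPHOBIC
HIS	CG	AROMATIC
HIS	ND1	AROMATIC,H_ACCEPTOR
HIS	CD2	AROMATIC
HIS	CE1	AROMATIC
HIS	NE2	AROMATIC,H_DONOR
ILE	CB	HYDROPHOBIC
ILE	CG1	HYDROPHOBIC
ILE	CG2	HYDROPHOBIC
ILE	CD1	HYDROPHOBIC
LEU	CB	HYDROPHOBIC
LEU	CG	HYDROPHOBIC
LEU	CD1	HYDROPHOBIC
LEU	CD2	HYDROPHOBIC
LYS	CB	HYDROPHOBIC
LYS	CG	HYDROPHOBIC
LYS	CD	HYDROPHOBIC
LYS	CE	HYDROPHOBIC
LYS	NZ	POSITIVE,H_DONOR
MET	CB	HYDROPHOBIC
MET	CG	HYDROPHOBIC
MET	SD	SULFUR
MET	CE	HYDROPHOBIC
MSE	CB	HYDROPHOBIC
MSE	CG	HYDROPHOBIC
MSE	SE	SULFUR
MSE	CE	HYDROPHOBIC
PHE	CB	HYDROPHOBIC
PHE	CG	AROMATIC,HYDROPHOBIC
PHE	CD1	AROMATIC,HYDROPHOBIC
PHE	CD2	AROMATIC,HYDROPHOBIC
PHE	CE1	AROMATIC,HYDROPHOBIC
PHE	CE2	AROMATIC,HYDROPHOBIC
PHE	CZ	AROMATIC,HYDROPHOBIC
PRO	N	NEUTRAL
PRO	CB	HYDROPHOBIC
PRO	CG	HYDROPHOBIC
PRO	CD	HYDROPHOBIC
SER	CB	HYDROPHOBIC
SER	OG	H_DONOR,H_ACCEPTOR
THR	CB	HYDROPHOBIC
THR	OG1	H_DONOR,H_ACCEPTOR
THR	CG2	HYDROPHOBIC
TRP	CB	HYDROPHOBIC
TRP	CG	AROMATIC
TRP	CD1	AROMATIC
TRP	CD2	AROMATIC,HYDROPHOBIC
TRP	NE1	AROMATIC,H_DONOR
TRP	CE2	AROMATIC
TRP	CE3	AROMATIC,HYDROPHOBIC
TRP	CZ2	AROMATIC,HYDROPHOBIC
TRP	CZ3	AROMATIC,HYDROPHOBIC
TRP	CH2	AROMATIC,HYDROPHOBIC
TYR	CB	HYDROPHOBIC
TYR	CG	AROMATIC,HYDROPHOBIC
TYR	CD1	AROMATIC,HYDROPHOBIC
TYR	CD2	AROMATIC,HYDROPHOBIC
TYR	CE1	AROMATIC,HYDROPHOBIC
TYR	CE2	AROMATIC,HYDROPHOBIC
TYR	CZ	AROMATIC
TYR	OH	H_DONOR,H_ACCEPTOR
VAL	CB	HYDROPHOBIC
VAL	CG1	HYDROPHOBIC
VAL	CG2	HYDROPHOBIC
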