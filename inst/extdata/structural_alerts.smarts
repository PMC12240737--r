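# Common structural alerts (reactive / toxic / uncommon substructures).
# One SMARTS per line, optional tab-separated label; '#' starts a comment.
# This is a curated subset of widely used medicinal-chemistry alerts and is
# user-replaceable; pass your own file to use a different alert collection.
[N+](=O)[O-]	nitro
[CX3H1](=O)[#6]	aldehyde
[CX3](=O)[F,Cl,Br,I]	acyl_halide
[OX2r3]1[#6r3][#6r3]1	epoxide
[NX3r3]1[#6r3][#6r3]1	aziridine
[NX2]=C=[OX1]	isocyanate
[NX2]=C=[SX1]	isothiocyanate
[#6][NX2]=[NX2][#6]	azo
[NX3;!$(N=O)][NX3;!$(N=O)]	hydrazine
[SX2H]	thiol
[CX4;!$(C(F)(F)F)][Cl,Br,I]	alkyl_halide
[OX2][OX2]	peroxide
[CX3]=[CX3][CX3]=[OX1]	michael_acceptor
S(=O)(=O)[F,Cl,Br,I]	sulfonyl_halide
[CX3](=O)[OX2][CX3](=O)	anhydride
[N+X4]	quaternary_ammonium
[#15]	phosphorus
[SX2][SX2]	disulfide
[NX3][NX2]=[CX3]	hydrazone
[NX2]=[OX1]	nitroso
[CX3]=[NX2][OX2H]	oxime
[NX3][CX3](=[SX1])[NX3]	thiourea
[CX3](=O)[CX4][Cl,Br,I]	alpha_halo_ketone
[NX2]=[N+X2]=[N-X1]	azide
[CX3]=[N+X2]=[N-X1]	diazo
S(=O)(=O)[OX2][#6]	sulfonate_ester
[CX2]#[CX2H]	terminal_alkyne
[OX1]=[CX3]([OX2H])[OX2H]	carbonic_acid
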