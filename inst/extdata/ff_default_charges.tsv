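# Default partial charge set for the zwitterionic FF unit, version 1.0.
# +1 e over the N-terminal NH3 group, -1 e over the C-terminal carboxylate,
# neutral partial-charge pairs on the peptide bond; all other atoms 0.
# Charges in elementary charges.  Quantum-chemical charges are out of scope;
# override per atom with a user table of the same shape.
residue_id	name	charge
1	N	-0.30
1	H1	0.4333333333333333
1	H2	0.4333333333333333
1	H3	0.4333333333333333
1	C	0.45
1	O	-0.45
2	N	-0.35
2	H	0.35
2	C	0.30
2	O	-0.65
2	OXT	-0.65
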