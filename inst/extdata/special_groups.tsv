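atom_type	neighbors	kind	lower	upper	units	description
H	H Acceptor	hbridge	0	1.75	angstrom	Intramolecular H bridge: acidic H (on O, N or S) to non-bonded acceptor (O, N or F) closer than 1.75 A
H	.H	hh_contact	0	2.0	angstrom	Intramolecular non-bonded H-H contact closer than 2.0 A
H	..H	hh_contact	2.0	2.3	angstrom	Intramolecular non-bonded H-H contact between 2.0 and 2.3 A
Angle60		ring_strain	0	74	degree	Ring-atom bond angle below 74 degrees (three-membered rings)
Angle90		ring_strain	74	98	degree	Ring-atom bond angle between 74 and 98 degrees (four-membered rings)
Angle102		ring_strain	98	106	degree	Ring-atom bond angle between 98 and 106 degrees
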