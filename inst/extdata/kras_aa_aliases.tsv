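nucleotide	amino_acid
9C>A	G12C
9C>T	G12S
9C>G	G12R
10C>T	G12D
10C>G	G12A
10C>A	G12V
12C>A	G13C
12C>T	G13S
12C>G	G13R
13C>T	G13D
13C>G	G13A
13C>A	G13V
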