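MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF WBOX_synthetic WRKY
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.850000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.050000 0.450000 0.050000 0.450000

MOTIF ABRE_synthetic bZIP
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.450000 0.450000
 0.050000 0.850000 0.050000 0.050000

MOTIF MYBCORE_synthetic MYB
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
 0.450000 0.050000 0.050000 0.450000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000

MOTIF HDZIP_synthetic HD-ZIP
letter-probability matrix: alength= 4 w= 9 nsites= 20 E= 0
 0.050000 0.850000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.450000 0.050000 0.050000 0.450000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.050000 0.850000
 0.050000 0.050000 0.850000 0.050000

MOTIF DOF_synthetic Dof-C2H2
letter-probability matrix: alength= 4 w= 5 nsites= 20 E= 0
 0.450000 0.050000 0.050000 0.450000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000

MOTIF GATA_synthetic GATA
letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0
 0.050000 0.050000 0.850000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.050000 0.850000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
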