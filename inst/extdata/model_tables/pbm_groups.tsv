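# Peptide-binding-motif (PBM) groups: clusters of allotypes with
# overlapping immunopeptidomes. Class I groups follow supertype-like
# clustering; the seven DRB1 groups follow hierarchical clustering of
# immunopeptidomics data. Curated/synthetic approximation for packaged
# alleles; replace with primary-source assignments for production use.
# Alleles absent from this table yield an NA (not classifiable) verdict.
allele	verdict
A*01:01	A-g1
A*25:01	A-g1
A*26:01	A-g1
A*32:01	A-g1
A*02:01	A-g2
A*68:02	A-g2
A*03:01	A-g3
A*11:01	A-g3
A*30:01	A-g3
A*31:01	A-g3
A*33:01	A-g3
A*68:01	A-g3
A*23:01	A-g4
A*24:02	A-g4
A*29:02	A-g4
B*07:02	B-g1
B*55:01	B-g1
B*56:01	B-g1
B*08:01	B-g2
B*27:05	B-g3
B*39:01	B-g3
B*18:01	B-g4
B*37:01	B-g4
B*40:01	B-g4
B*40:02	B-g4
B*44:02	B-g4
B*44:03	B-g4
B*13:02	B-g5
B*57:01	B-g5
B*58:01	B-g5
B*35:01	B-g6
B*35:02	B-g6
B*35:03	B-g6
B*35:08	B-g6
B*53:01	B-g6
B*15:01	B-g7
B*52:01	B-g7
B*38:01	B-g8
B*51:01	B-g8
B*14:01	B-g9
B*14:02	B-g9
C*03:03	C-g1
C*03:04	C-g1
C*07:01	C-g2
C*07:02	C-g2
C*07:04	C-g2
C*04:01	C-g3
C*05:01	C-g4
C*08:02	C-g4
C*06:02	C-g5
C*12:03	C-g6
C*16:01	C-g6
C*01:02	C-g7
C*02:02	C-g7
C*15:02	C-g7
DRB1*01:01	DR-g1
DRB1*01:02	DR-g1
DRB1*10:01	DR-g1
DRB1*15:01	DR-g2
DRB1*15:02	DR-g2
DRB1*16:01	DR-g2
DRB1*03:01	DR-g3
DRB1*04:01	DR-g4
DRB1*04:04	DR-g4
DRB1*11:01	DR-g5
DRB1*11:04	DR-g5
DRB1*13:03	DR-g5
DRB1*14:01	DR-g5
DRB1*14:54	DR-g5
DRB1*13:01	DR-g6
DRB1*13:02	DR-g6
DRB1*07:01	DR-g7
DRB1*09:01	DR-g7
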