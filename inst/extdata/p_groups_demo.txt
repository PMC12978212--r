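# hla_nom_p miniature fixture: P-group list in the IPD-IMGT/HLA dialect
# file: hla_nom_p.txt
# Covers the alleles used by the packaged haplotype presets and examples.
# Format: locus*;allele/allele/...;P-group (empty group = singleton).
A*;01:01:01:01/01:01:01:02N/01:01:02;01:01P
A*;02:01:01:01/02:01:01:02L/02:01:02;02:01P
A*;03:01:01:01/03:01:01:02;03:01P
A*;11:01:01/11:01:02;11:01P
A*;24:02:01:01/24:02:01:02L;24:02P
A*;36:01;
B*;07:02:01/07:02:02;07:02P
B*;08:01:01;08:01P
B*;35:01:01:01/35:01:01:02;35:01P
B*;35:02:01;35:02P
B*;35:03:01;35:03P
B*;44:02:01:01/44:02:01:03;44:02P
B*;44:03:01/44:03:02;44:03P
C*;03:03:01;03:03P
C*;03:04:01:01/03:04:01:02;03:04P
C*;07:01:01/07:01:02;07:01P
C*;07:02:01:01/07:02:01:03;07:02P
DRB1*;11:01:01/11:01:02;11:01P
DRB1*;11:04:01;11:04P
DRB1*;04:01:01;04:01P
DRB1*;04:04:01;04:04P
DRB1*;14:01:01/14:54:01;14:01P
DQB1*;03:01:01:01/03:01:01:02/03:01:01:03;03:01P
DQB1*;03:02:01;03:02P
DQB1*;06:02:01;06:02P
DPB1*;02:01:02/02:01:03;02:01P
DPB1*;04:01:01:01/04:01:01:02/04:01:31;04:01P
DPB1*;04:02:01:01/04:02:01:02;04:02P
DPA1*;01:03:01:01/01:03:01:02;01:03P
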