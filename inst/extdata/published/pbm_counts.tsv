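# Reported PBM-GvH matching counts among 9/10 single mismatches at class I
# and DRB1 (registry cohort; NA = assignment not possible for lack of
# primary immunopeptidomics data).
locus	pbm_gvh	n
A	matched	523
A	mismatched	1278
A	NA	262
B	matched	342
B	mismatched	507
B	NA	203
C	matched	491
C	mismatched	638
C	NA	219
DRB1	matched	399
DRB1	mismatched	135
DRB1	NA	60
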