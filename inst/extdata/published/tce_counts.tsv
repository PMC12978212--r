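# Reported directional DPB1 TCE matching subset counts by match-grade
# category (registry cohort, N = 28,376).
tce_subset	category	n
allele-matched	10/10	6404
allele-matched	9/10	1010
allele-matched	8/10	109
allele-matched	<8/10	21
core permissive	10/10	4169
core permissive	9/10	1316
core permissive	8/10	177
core permissive	<8/10	33
non-core permissive HvG	10/10	1581
non-core permissive HvG	9/10	433
non-core permissive HvG	8/10	68
non-core permissive HvG	<8/10	7
non-core permissive GvH	10/10	2222
non-core permissive GvH	9/10	656
non-core permissive GvH	8/10	98
non-core permissive GvH	<8/10	20
other permissive	10/10	633
other permissive	9/10	200
other permissive	8/10	35
other permissive	<8/10	2
non-permissive HvG	10/10	2349
non-permissive HvG	9/10	919
non-permissive HvG	8/10	131
non-permissive HvG	<8/10	25
non-permissive GvH	10/10	3952
non-permissive GvH	9/10	1519
non-permissive GvH	8/10	237
non-permissive GvH	<8/10	50
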