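# Reported patient-donor HLA matching counts for a 28,376-pair European
# registry cohort of first unrelated-donor transplants (6-locus
# high-resolution typing).
category	n
10/10	21310
9/10	6053
8/10	855
<8/10	158
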