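# HLA-B leader peptide position -21 residue (methionine M / threonine T).
# Curated table covering the alleles used by the packaged presets.
allele	verdict
B*07:02	M
B*07:05	M
B*08:01	M
B*14:01	M
B*14:02	M
B*18:01	M
B*35:01	M
B*35:02	M
B*35:03	M
B*35:08	M
B*39:01	M
B*39:06	M
B*41:01	M
B*42:01	M
B*48:01	M
B*54:01	M
B*55:01	M
B*56:01	M
B*67:01	M
B*81:01	M
B*13:02	T
B*15:01	T
B*27:05	T
B*37:01	T
B*38:01	T
B*40:01	T
B*40:02	T
B*44:02	T
B*44:03	T
B*45:01	T
B*49:01	T
B*50:01	T
B*51:01	T
B*52:01	T
B*53:01	T
B*57:01	T
B*58:01	T
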