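Package: hlamatchr
Title: HLA Mismatch Landscapes and Functional Matching for Unrelated-Donor
    Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises HLA mismatching in unrelated-donor haematopoietic
    cell transplant pairs at multiple levels: WHO nomenclature parsing with
    two-field reduction and the null-allele homozygosity rule, per-locus
    mismatch enumeration with graft-versus-host and host-versus-graft
    direction vectors, 10/10 and 12/12 match grades, allelic versus antigenic
    resolution, and seven functional matching models (antigen-recognition
    domain P-groups, peptide-binding-motif GvH matching, HLA-B leader -21 M/T
    dimorphism, HLA-DPB1 T-cell epitope permissiveness with core/non-core
    direction, rs9277534-linked expression, and TPHE). Provides cohort-level
    landscape analytics (allele frequencies, mismatch-combination tables,
    representation ratios, era-stratified matching), a Kruskal-Wallis/Dunn
    comparison of diagnosis-to-transplant times, and a registry-like
    synthetic cohort generator with haplotype linkage disequilibrium and
    donor-selection pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
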