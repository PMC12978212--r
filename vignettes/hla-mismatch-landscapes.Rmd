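---
title: "Characterising HLA mismatch landscapes in unrelated-donor transplantation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising HLA mismatch landscapes in unrelated-donor transplantation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlamatchr)
library(dplyr)
```

## The problem

Unrelated-donor haematopoietic cell transplantation depends on HLA
compatibility between patient and donor. Registries type both subjects at
high resolution at six loci — HLA-A, -B, -C, -DRB1, -DQB1 (the five "main"
loci that define the x/10 match grade) and HLA-DPB1 (extending it to
x/12) — yet a quarter of transplants are performed across one or more
main-locus mismatches. Not all mismatches are equal: alleles that differ
in name may encode the same antigen-recognition domain, present
overlapping peptide repertoires, or fall into permissive T-cell epitope
configurations. This package provides a tested pipeline that takes a
cohort table of paired 6-locus genotypes and characterises every mismatch
at the allelic, antigenic and functional levels, then aggregates
cohort-level landscapes and statistics.

## Mismatch enumeration

Allele names follow WHO nomenclature (`LOCUS*F1:F2[:F3[:F4]][SUFFIX]`).
Analysis operates at two-field (protein) resolution: higher-resolution
names are truncated (and flagged), one-field names are flagged so callers
can exclude them, and a subject carrying a null (`N`-suffixed) allele is
treated as homozygous for the expressed partner allele.

At each locus the mismatch count is 2 minus the size of a maximum matching
between the two 2-element allele multisets under two-field equality. Two
complementary views of "unmatched" are kept deliberately distinct:

* **Direction vectors** use allele *types*: the GvH vector holds patient
  alleles whose type is absent from the donor (targets for donor T cells),
  the HvG vector the converse. A patient homozygous for `A*01:01` facing a
  donor `A*01:01, A*02:01` has a single HvG-only mismatch — the donor's
  unshared `A*02:01` — and no GvH target.
* **Unmatched pairings** come from the maximum-matching leftovers, one
  (donor allele, patient allele) pair per counted mismatch. These drive
  the resolution label (allelic when the pair shares its first field,
  antigenic otherwise) and the combination landscapes. When the two
  pairings are equally good, identical-first-field alleles are paired
  together, then input order (lexicographic after genotype normalisation)
  decides — a deterministic tie-break so landscape tables are stable.

Match grades follow registry convention: `grade10` is 10 minus the total
mismatch count over the five main loci, `grade12` adds DPB1, and the
mismatched-locus multiset distinguishes an 8/10 from a double mismatch at
one locus versus single mismatches at two.

## The seven functional models

All models are table-driven behind one `hla_reference()` object.

* **ARD (P-group) matching** — mismatched allele pairings within one
  P-group (identical protein sequence over exons 2 and 3 for class I,
  exon 2 for class II) are functionally equivalent. P-groups are read from
  a file in the exact IPD-IMGT/HLA `hla_nom_p.txt` dialect, so the real
  release file can be dropped in; a miniature copy ships for
  self-containment.
* **PBM-GvH matching** — for single class I or DRB1 mismatches, the pair
  is matched when every patient allotype's peptide-binding-motif group is
  represented among the donor's allotypes. Allotypes without a PBM
  assignment yield `NA`, reported as their own category.
* **B-leader matching** — single HLA-B mismatches are classified by the
  methionine/threonine dimorphism at position −21 of the leader peptide,
  with the full three-residue genotype string (shared, patient, donor)
  reported.
* **TCE model** — each subject's most immunogenic DPB1 T-cell epitope
  group is the minimum group over their two alleles (1 < 2 < 3); equal
  minima are permissive, otherwise the side carrying the more immunogenic
  group fixes the non-permissive direction.
* **Core/non-core subclassification** — permissive mismatches confined to
  the structurally similar core subset of TCE group 3 are "core";
  a non-core TCE3 allele among the patient's (donor's) mismatched alleles
  gives a GvH (HvG) direction; residual configurations — non-core on both
  sides, or mismatched alleles outside TCE group 3 — are "other
  permissive". The residual rule is a package decision: it is the reading
  that yields exactly the seven directional labels used in registry
  reports, and it is isolated in `tce_core_subclassify()` so an
  alternative rule is a one-function change.
* **Expression model** — applicable to single DPB1 mismatches with a GvH
  component; the verdict is the rs9277534 linkage of the patient's
  mismatched allele (G-linked high, A-linked low). The applicability rule
  is not standardised in the literature we follow; this choice is recorded
  per pair so cohort applicability is auditable.
* **TPHE** — permissive and high-expression combined; any unknown input
  propagates to `NA`.

Unknown lookups never default silently: every model emits an explicit
`NA`/`unknown` category that the summary tables report.

### Provenance of the packaged tables

The TCE group, core-TCE3 and rs9277534 linkage tables follow the published
models for the common European alleles they cover. The PBM groups and some
B-leader residues are curated approximations assembled for the packaged
allele universe: they respect the constraints the models imply (P-group
identical alleles share a PBM group; the classic C*03:03/C*03:04 pair is
PBM-matched) but should be replaced with primary-source assignments, via
`hla_reference(tables_dir = ...)`, for production analyses.

## Cohort analytics

`annotate_cohort()` performs the whole per-pair pipeline and returns one
tidy row per retained pair; rows with unusable typing (missing alleles,
unparseable names, one-field resolution, double-null genotypes) are
excluded with per-row reasons — mirroring the registry inclusion rule that
requires complete 6-locus typing — and the exclusions are attached and
logged, never silent.

Landscape analytics follow registry conventions: allele frequencies by
direct counting over 2N chromosomes; mismatch combinations tallied as
ordered (donor, patient) pairs over the pairs mismatched at the locus
(DPB1 landscapes stratified within 10/10 and 9/10); a direction-merged
view for combination families reported direction-free; representation
ratios comparing an allele's frequency among mismatched alleles with its
cohort frequency. Percentages are rounded half-up to one decimal, the
style of registry tables; two published boundary cases (a 25.35 printed as
25.3, a 69.95 printed as 70) differ from this convention in the last
digit.

Diagnosis-to-transplant times are compared between 10/10 and <10/10 pairs
stratified by transplant era (pre-2011, 2011–2015, 2016–2020, 2021–2022)
with a Kruskal–Wallis omnibus test and Dunn's post hoc z tests on pooled
mid-ranks with tie-corrected variance. The adjustment family is the four
within-era contrasts — the only contrasts of scientific interest here —
under Bonferroni by default; both family and method are arguments. The
conventional significance level is p < 0.01.

## The synthetic cohort generator

No registry cohort is distributable, so `sample_cohort()` generates one
with the structural features the pipeline must handle:

* **Haplotype pool with LD.** Patients are two independent draws from a
  6-locus haplotype pool (Hardy–Weinberg at the haplotype level; no
  within-haplotype recombination). The `euro-toy` preset (32 haplotypes)
  caricatures common European haplotypes: a few frequent 5-locus
  backgrounds, single-locus allelic variants of those backgrounds (the
  near-miss haplotypes that make 9/10 matches and skewed class II
  landscapes possible — DRB1\*14:01/14:54, DRB1\*11:01/11:04,
  C\*03:03/03:04, the B\*35 family), and DPB1 variation within backgrounds
  so DPB1 mismatch is common among otherwise fully matched pairs. `ld =
  FALSE` draws each locus independently from the marginals, the null used
  for representation-ratio properties.
* **Donor selection.** Each patient searches `registry_size` independent
  registry genotypes; the default policy keeps the best 10/10 grade (ties
  seed-deterministically to the first candidate). The default
  `registry_size = 250` was chosen once as the search depth that, against
  the euro-toy pool's diversity, yields a contemporary registry-like grade
  mix (roughly two-thirds 10/10, a sixth 9/10); `random` and
  `grade-threshold` policies support null and satisficing designs.
* **Clinical covariates.** Era weights default to 9/18/49/24% across the
  four eras; PTCy adoption rises 0/2/10/22%; times from diagnosis to
  transplant are log-normal (sdlog 0.6) with matching-status-dependent
  medians anchored at 14.9 vs 11.3 months in the earliest era narrowing to
  8.1 vs 7.4 in the latest, middle eras interpolated.

All draws flow from one seeded generator: a fixed seed reproduces the
cohort byte for byte.

What the generator does *not* emulate: real-world allele diversity (tens
of alleles per locus, rare-allele tails), population substructure and
ethnicity effects, registry attrition and search failure (patients who
never reach transplant), era-dependent typing quality, or correlations
between HLA and disease. Passing tests therefore demonstrate that the
pipeline's logic and statistics behave correctly under controlled
conditions — not that any specific frequency estimate transfers to real
registry data.

## Numerical and degenerate-input choices

* Mismatch-count ties between pairings: first-field pairing preferred,
  then lexicographic; deterministic landscapes.
* Genotypes with two null alleles are an error, not a guess — their
  handling in registry practice is undefined, so the row is excluded and
  reported.
* Empty cohorts summarise to zero counts with `NA` (flagged) rates;
  zero-denominator percentages are always `NA`, never 0.
* Contrasts with an empty group are reported with `NA` statistics rather
  than dropped.
* Dunn p values are two-sided normal tails; adjusted values are capped at
  1; mid-ranks with the $\sum_t (t^3-t)/(12(N-1))$ tie correction.

## Problem sizes

The shipped tests run the exhaustive oracles (all 625 genotype pairs of a
5-allele toy set against brute-force pairing; all 1,296 ordered DPB1
genotype pairs of a 6-allele fixture against the min-group rule), a
1,000-replicate type-I calibration of the era comparison, and synthetic
cohorts of 800–4,000 pairs for the simulation properties. The acceptance
script uses a 12,000-pair cohort so that era strata are comparable in size
to the registry strata it emulates.

## Known limitations

* The packaged model tables cover the preset allele universe, not the full
  IPD-IMGT/HLA catalogue; out-of-table alleles flow to `NA` categories by
  design.
* PBM groups are curated approximations (see above).
* Third/fourth-field differences, serological splits, and eplet- or
  KIR-based models are out of scope.
* The expression-model applicability rule (single GvH-direction DPB1
  mismatch) is one of several defensible readings; it is recorded in the
  output so downstream users can recompute applicability under another
  rule.
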