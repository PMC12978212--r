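# The seven functional matching models applied to allele-mismatched pairs:
# ARD (P-group) matching, PBM-GvH matching, B-leader -21 M/T matching, the
# bidirectional DPB1 TCE model with core/non-core subclassification of
# permissive mismatches, the rs9277534-linked expression model, and the
# combined TPHE classification.  Unknown table lookups never default; they
# propagate to NA/unknown verdicts.

#' Antigen-recognition-domain (P-group) matching of a mismatch
#'
#' A mismatch is ARD matched when every unmatched allele pairing lies within
#' a single P-group, i.e. the mismatched alleles encode the same
#' peptide-binding-domain protein sequence (exons 2 and 3 for class I, exon
#' 2 for class II) and are expected to be functionally equivalent.
#'
#' @param record A `mismatch_record` with `count >= 1` at one of the five
#'   main loci.
#' @param reference An [hla_reference()].
#' @return `"matched"` or `"mismatched"`.
#' @examples
#' ref <- default_reference()
#' p <- normalize_genotype("DRB1", "DRB1*14:01", "DRB1*03:01")
#' d <- normalize_genotype("DRB1", "DRB1*14:54", "DRB1*03:01")
#' ard_match(locus_mismatch(p, d), ref) # same P-group 14:01P
#' @export
ard_match <- function(record, reference) {
  stopifnot(inherits(record, "mismatch_record"))
  if (!record$locus %in% MAIN_LOCI) {
    abort("ARD matching applies to the five main loci (A, B, C, DRB1, DQB1)")
  }
  if (record$count < 1) {
    abort("ARD matching is defined only for mismatched loci (count >= 1)")
  }
  same <- p_group_of(record$pairing$donor, reference$p_groups) ==
    p_group_of(record$pairing$patient, reference$p_groups)
  if (all(same)) "matched" else "mismatched"
}

pbm_covered <- function(p_allele, donor_keys, reference) {
  if (p_allele %in% donor_keys) return(TRUE)
  g <- unname(reference$pbm_group[p_allele])
  dg <- unname(reference$pbm_group[donor_keys])
  if (is.na(g)) return(NA)
  if (g %in% dg[!is.na(dg)]) return(TRUE)
  if (any(is.na(dg))) return(NA)
  FALSE
}

#' Peptide-binding-motif matching in the GvH direction
#'
#' For a single mismatch at HLA-A, -B, -C or -DRB1, the pair is PBM-GvH
#' matched when every patient allotype's PBM group is represented among the
#' donor's allotypes (the donor immunopeptidome covers the patient's). `NA`
#' when a required allotype lacks a PBM assignment.
#'
#' @param patient,donor `locus_genotype` objects at the same locus.
#' @param reference An [hla_reference()].
#' @return `"matched"`, `"mismatched"` or `NA`.
#' @export
pbm_gvh_match <- function(patient, donor, reference) {
  if (!patient$locus %in% c(CLASS1_LOCI, "DRB1")) {
    abort("PBM-GvH matching applies to HLA-A, -B, -C and -DRB1 only")
  }
  rec <- locus_mismatch(patient, donor)
  if (rec$count != 1) {
    abort("PBM-GvH matching is defined for single-mismatch genotypes")
  }
  donor_keys <- c(donor$allele_a, donor$allele_b)
  cov <- c(
    pbm_covered(patient$allele_a, donor_keys, reference),
    pbm_covered(patient$allele_b, donor_keys, reference)
  )
  if (any(!cov, na.rm = TRUE)) return("mismatched")
  if (any(is.na(cov))) return(NA_character_)
  "matched"
}

#' B-leader peptide -21 M/T classification of a single HLA-B mismatch
#'
#' The mismatched alleles are leader-matched when they carry the same
#' methionine/threonine residue at position -21 of the HLA-B leader peptide.
#' The genotype string gives the residues of (shared allele, patient
#' mismatched allele, donor mismatched allele), e.g. `"TTT"`.
#'
#' @param patient,donor `locus_genotype` objects at HLA-B with a single
#'   mismatch.
#' @param reference An [hla_reference()].
#' @return A list with `verdict` (`"matched"`, `"mismatched"` or `NA`) and
#'   `genotype` (three-letter residue string, `NA` when any residue is
#'   unknown).
#' @export
b_leader_classify <- function(patient, donor, reference) {
  if (patient$locus != "B" || donor$locus != "B") {
    abort("B-leader classification applies to HLA-B only")
  }
  rec <- locus_mismatch(patient, donor)
  if (rec$count != 1) {
    abort("B-leader classification is defined for single-B-mismatch genotypes")
  }
  p_mm <- rec$pairing$patient[1]
  d_mm <- rec$pairing$donor[1]
  shared <- setdiff(c(patient$allele_a, patient$allele_b), p_mm)
  if (length(shared) == 0) shared <- patient$allele_a # homozygous leftover
  res <- unname(reference$leader[c(shared[1], p_mm, d_mm)])
  verdict <- if (any(is.na(res[2:3]))) NA_character_ else {
    if (res[2] == res[3]) "matched" else "mismatched"
  }
  genotype <- if (any(is.na(res))) NA_character_ else paste0(res, collapse = "")
  list(verdict = verdict, genotype = genotype)
}

tce_min_group <- function(keys, reference) {
  g <- suppressWarnings(as.integer(reference$tce_group[keys]))
  if (any(is.na(g))) NA_integer_ else min(g)
}

#' Bidirectional TCE classification of a DPB1 genotype pair
#'
#' Each subject's most immunogenic TCE group is the minimum group (1 <
#' 2 < 3) over their two DPB1 alleles. Allele-matched pairs have no DPB1
#' mismatch; mismatched pairs are permissive when the two minima coincide,
#' non-permissive GvH when the patient carries the more immunogenic group,
#' and non-permissive HvG when the donor does.
#'
#' @param patient,donor `locus_genotype` objects at DPB1.
#' @param reference An [hla_reference()].
#' @return One of `"allele-matched"`, `"permissive"`,
#'   `"non-permissive GvH"`, `"non-permissive HvG"`, `"unknown"`.
#' @export
tce_classify <- function(patient, donor, reference) {
  if (patient$locus != "DPB1" || donor$locus != "DPB1") {
    abort("TCE classification applies to HLA-DPB1 only")
  }
  rec <- locus_mismatch(patient, donor)
  if (rec$count == 0) return("allele-matched")
  mp <- tce_min_group(c(patient$allele_a, patient$allele_b), reference)
  md <- tce_min_group(c(donor$allele_a, donor$allele_b), reference)
  if (is.na(mp) || is.na(md)) return("unknown")
  if (mp == md) "permissive" else if (mp < md) "non-permissive GvH" else "non-permissive HvG"
}

#' Core/non-core subclassification of a permissive DPB1 mismatch
#'
#' Permissive mismatches confined to the structurally similar "core" subset
#' of TCE group 3 alleles are `"core"`. A non-core TCE3 allele among the
#' patient's mismatched alleles makes the mismatch `"non-core GvH"` (the
#' graft sees it), among the donor's `"non-core HvG"`. Residual permissive
#' configurations (non-core on both sides, or mismatched alleles outside
#' TCE group 3) are `"other"`.
#'
#' @inheritParams tce_classify
#' @return `"core"`, `"non-core GvH"`, `"non-core HvG"`, `"other"` or
#'   `"unknown"`.
#' @export
tce_core_subclassify <- function(patient, donor, reference) {
  verdict <- tce_classify(patient, donor, reference)
  if (verdict != "permissive") {
    abort("Core/non-core subclassification applies to permissive mismatches only")
  }
  pk <- c(patient$allele_a, patient$allele_b)
  dk <- c(donor$allele_a, donor$allele_b)
  p_mm <- unique(setdiff(pk, dk))
  d_mm <- unique(setdiff(dk, pk))
  side_status <- function(keys) {
    if (length(keys) == 0) {
      return(list(all_tce3 = TRUE, noncore = FALSE, unknown = FALSE))
    }
    g <- suppressWarnings(as.integer(reference$tce_group[keys]))
    core <- unname(reference$core_tce3[keys])
    tce3 <- !is.na(g) & g == 3L
    list(
      all_tce3 = all(tce3),
      noncore = any(tce3 & !is.na(core) & core == "non-core"),
      unknown = any(tce3 & is.na(core))
    )
  }
  ps <- side_status(p_mm)
  ds <- side_status(d_mm)
  if (ps$unknown || ds$unknown) return("unknown")
  if (!ps$all_tce3 || !ds$all_tce3) return("other")
  if (ps$noncore && ds$noncore) return("other")
  if (ps$noncore) return("non-core GvH")
  if (ds$noncore) return("non-core HvG")
  "core"
}

#' Expression-model classification of a single DPB1 mismatch
#'
#' Applicable to pairs with a single DPB1 mismatch that has a GvH component;
#' the verdict is the rs9277534 linkage of the patient's mismatched allele
#' (G-linked = high expression, A-linked = low). `NA` otherwise (double
#' mismatches, allele-matched or HvG-only pairs, unknown linkage).
#'
#' @inheritParams tce_classify
#' @return `"high"`, `"low"` or `NA`.
#' @export
expression_classify <- function(patient, donor, reference) {
  if (patient$locus != "DPB1" || donor$locus != "DPB1") {
    abort("Expression classification applies to HLA-DPB1 only")
  }
  rec <- locus_mismatch(patient, donor)
  if (rec$count != 1) return(NA_character_)
  gvh <- rec$unmatched_patient_alleles
  if (length(gvh) == 0) return(NA_character_)
  unname(reference$expression[gvh[1]])
}

#' TPHE classification
#'
#' TCE-permissive, high-expression (TPHE) DPB1 mismatches combine the TCE
#' and expression model verdicts.
#'
#' @param tce A TCE verdict from [tce_classify()].
#' @param expression An expression verdict from [expression_classify()].
#' @return `"TPHE"`, `"other"` or `NA` (when either input is NA/unknown).
#' @export
tphe_classify <- function(tce, expression) {
  dplyr::case_when(
    is.na(tce) | tce == "unknown" | is.na(expression) ~ NA_character_,
    tce == "permissive" & expression == "high" ~ "TPHE",
    .default = "other"
  )
}
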