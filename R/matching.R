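# Per-locus mismatch enumeration.
#
# The mismatch count at a locus is 2 minus the size of a maximum matching
# between the two 2-element allele multisets under two-field equality (for
# 2x2 this is the better of the two possible pairings).  Direction vectors
# use allele types: the GvH vector holds patient alleles whose type is absent
# from the donor's type set (targets for donor T cells), the HvG vector the
# converse.  The unmatched allele *pairings* used for resolution labelling
# and the combination landscapes come from the maximum-matching leftovers,
# tie-broken by pairing identical first fields together, then lexicographic.

ff_of_key <- function(key) stringr::str_remove(key, ":[0-9]+$")

# vectorised mismatch over two-field allele keys; the workhorse behind
# cohort annotation.  All inputs are equal-length character vectors.
mismatch_vec <- function(p1, p2, d1, d2) {
  scoreA <- (p1 == d1) + (p2 == d2)
  scoreB <- (p1 == d2) + (p2 == d1)
  best <- pmax(scoreA, scoreB)
  count <- 2L - best

  # tie-break between equally good pairings: prefer the one whose leftover
  # pairs share first fields, else keep input (lexicographic) order
  ffp1 <- ff_of_key(p1); ffp2 <- ff_of_key(p2)
  ffd1 <- ff_of_key(d1); ffd2 <- ff_of_key(d2)
  ffA <- (p1 != d1) * (ffp1 == ffd1) + (p2 != d2) * (ffp2 == ffd2)
  ffB <- (p1 != d2) * (ffp1 == ffd2) + (p2 != d1) * (ffp2 == ffd1)
  useB <- (scoreB > scoreA) | (scoreB == scoreA & ffB > ffA)

  q1 <- ifelse(useB, d2, d1)
  q2 <- ifelse(useB, d1, d2)
  # leftover pairs (patient allele, paired donor allele) where they differ
  m1 <- p1 != q1
  m2 <- p2 != q2
  pu <- paste_slash(ifelse(m1, p1, NA), ifelse(m2, p2, NA))
  du <- paste_slash(ifelse(m1, q1, NA), ifelse(m2, q2, NA))

  # direction by type-set membership, with genotype multiplicity
  g1 <- p1 != d1 & p1 != d2
  g2 <- p2 != d1 & p2 != d2
  h1 <- d1 != p1 & d1 != p2
  h2 <- d2 != p1 & d2 != p2
  gvh <- paste_slash(ifelse(g1, p1, NA), ifelse(g2, p2, NA))
  hvg <- paste_slash(ifelse(h1, d1, NA), ifelse(h2, d2, NA))
  direction <- dplyr::case_when(
    gvh != "" & hvg != "" ~ "bidirectional",
    gvh != "" ~ "GvH",
    hvg != "" ~ "HvG",
    .default = "none"
  )
  tibble(count = count, direction = direction, gvh = gvh, hvg = hvg,
         pu = pu, du = du)
}

paste_slash <- function(a, b) {
  out <- ifelse(is.na(a), ifelse(is.na(b), "", b),
                ifelse(is.na(b), a, paste(a, b, sep = "/")))
  out
}

split_slash <- function(x) {
  if (length(x) == 1 && (is.na(x) || x == "")) return(character(0))
  stringr::str_split_1(x, stringr::fixed("/"))
}

#' Enumerate the mismatch at one locus of a patient-donor pair
#'
#' @param patient,donor `locus_genotype` objects (see [normalize_genotype()])
#'   for the same locus.
#' @return A list of class `mismatch_record`: `locus`, `count` (0, 1 or 2),
#'   `unmatched_patient_alleles` (the GvH vector), `unmatched_donor_alleles`
#'   (the HvG vector), `direction` (`none`, `GvH`, `HvG`, `bidirectional`),
#'   and `pairing`, a tibble of the unmatched (donor, patient) allele
#'   pairings with their `resolution` (`allelic` = antigen-level matched,
#'   `antigenic` = first-field mismatch).
#' @examples
#' p <- normalize_genotype("C", "C*03:03", "C*07:01")
#' d <- normalize_genotype("C", "C*03:04", "C*07:01")
#' locus_mismatch(p, d)
#' @export
locus_mismatch <- function(patient, donor) {
  stopifnot(inherits(patient, "locus_genotype"), inherits(donor, "locus_genotype"))
  if (patient$locus != donor$locus) {
    abort("patient and donor genotypes are at different loci")
  }
  v <- mismatch_vec(patient$allele_a, patient$allele_b,
                    donor$allele_a, donor$allele_b)
  pu <- split_slash(v$pu)
  du <- split_slash(v$du)
  pairing <- tibble(
    donor = du, patient = pu,
    resolution = ifelse(ff_of_key(du) == ff_of_key(pu), "allelic", "antigenic")
  )
  structure(
    list(
      locus = patient$locus,
      count = v$count,
      unmatched_patient_alleles = split_slash(v$gvh),
      unmatched_donor_alleles = split_slash(v$hvg),
      direction = v$direction,
      pairing = pairing
    ),
    class = "mismatch_record"
  )
}

#' @export
print.mismatch_record <- function(x, ...) {
  cat(sprintf("<mismatch_record %s: count %d, %s>\n", x$locus, x$count, x$direction))
  if (x$count > 0) print(x$pairing)
  invisible(x)
}

#' Resolution of a single mismatch
#'
#' A single mismatch is *antigen-level matched* ("low-resolution matched",
#' returned as `"allelic"`) when the unmatched donor and patient alleles
#' share their first field, and an antigenic (low-resolution) mismatch
#' (`"antigenic"`) otherwise.
#'
#' @param record A `mismatch_record` with `count == 1`.
#' @return `"allelic"` or `"antigenic"`.
#' @export
classify_resolution <- function(record) {
  stopifnot(inherits(record, "mismatch_record"))
  if (record$count != 1) {
    abort("Resolution is defined only for single mismatches (count == 1)")
  }
  record$pairing$resolution[1]
}

#' Match grade of a six-locus pair
#'
#' @param patient,donor Named lists of `locus_genotype` objects covering all
#'   six loci (`A`, `B`, `C`, `DRB1`, `DQB1`, `DPB1`).
#' @return A list of class `match_grade`: `grade10` (matched alleles over the
#'   five main loci), `grade12` (adding DPB1), `dpb1_status` (`matched`,
#'   `single mismatch`, `double mismatch`), `category` (`10/10`, `9/10`,
#'   `8/10`, `<8/10`), `mm_loci` (mismatched main loci with multiplicity) and
#'   `mm_class` (`none`, `class I`, `class II`, `mixed`).
#' @export
match_grade <- function(patient, donor) {
  stopifnot(all(HLA_LOCI %in% names(patient)), all(HLA_LOCI %in% names(donor)))
  counts <- vapply(HLA_LOCI, function(l) {
    locus_mismatch(patient[[l]], donor[[l]])$count
  }, integer(1))
  grade_from_counts(counts["A"], counts["B"], counts["C"],
                    counts["DRB1"], counts["DQB1"], counts["DPB1"])
}

grade_from_counts <- function(a, b, c, drb1, dqb1, dpb1) {
  main <- a + b + c + drb1 + dqb1
  grade10 <- 10L - as.integer(main)
  grade12 <- grade10 + (2L - as.integer(dpb1))
  category <- dplyr::case_when(
    grade10 == 10L ~ "10/10",
    grade10 == 9L ~ "9/10",
    grade10 == 8L ~ "8/10",
    .default = "<8/10"
  )
  mm <- c(A = unname(a), B = unname(b), C = unname(c),
          DRB1 = unname(drb1), DQB1 = unname(dqb1))
  mm_loci <- rep(names(mm), mm)
  class1 <- sum(mm[CLASS1_LOCI])
  class2 <- sum(mm[CLASS2_LOCI])
  mm_class <- dplyr::case_when(
    class1 > 0 & class2 > 0 ~ "mixed",
    class1 > 0 ~ "class I",
    class2 > 0 ~ "class II",
    .default = "none"
  )
  structure(
    list(
      grade10 = grade10, grade12 = grade12,
      dpb1_status = c("matched", "single mismatch", "double mismatch")[dpb1 + 1L],
      category = factor(category, CATEGORY_LEVELS),
      mm_loci = mm_loci,
      n_mm_loci = length(unique(mm_loci)),
      mm_class = mm_class
    ),
    class = "match_grade"
  )
}

#' @export
print.match_grade <- function(x, ...) {
  cat(sprintf("<match_grade %d/10, %d/12 (%s; DPB1 %s)>\n",
              x$grade10, x$grade12, x$mm_class, x$dpb1_status))
  invisible(x)
}

#' Transplant era of a year
#'
#' Buckets transplant years into the four eras used for cohort
#' stratification: `pre-2011`, `2011-2015`, `2016-2020`, `2021-2022`.
#'
#' @param year Integer vector of transplant years (the cohort definition
#'   ends in 2022; later years are an error).
#' @return Factor with the four era levels (`NA` for missing years).
#' @export
era_of <- function(year) {
  if (any(!is.na(year) & (year > 2022 | year < 1900))) {
    abort("Transplant year outside the supported range (.. 2022)")
  }
  out <- dplyr::case_when(
    is.na(year) ~ NA_character_,
    year <= 2010 ~ "pre-2011",
    year <= 2015 ~ "2011-2015",
    year <= 2020 ~ "2016-2020",
    .default = "2021-2022"
  )
  factor(out, ERA_LEVELS)
}
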