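# independent oracle: best of the two possible pairings of two 2-element
# allele multisets
brute_mismatch_count <- function(p, d) {
  2L - max(sum(p == d), sum(p == rev(d)))
}

test_that("mismatch counting equals the exhaustive pairing oracle", {
  toy <- paste0("A*0", 1:5, ":01")
  combos <- expand.grid(p1 = toy, p2 = toy, d1 = toy, d2 = toy,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    p <- normalize_genotype("A", combos$p1[i], combos$p2[i])
    d <- normalize_genotype("A", combos$d1[i], combos$d2[i])
    rec <- locus_mismatch(p, d)
    expected <- brute_mismatch_count(c(p$allele_a, p$allele_b),
                                     c(d$allele_a, d$allele_b))
    expect_identical(rec$count, expected)

    # count equals the larger direction vector
    expect_identical(rec$count,
                     max(length(rec$unmatched_patient_alleles),
                         length(rec$unmatched_donor_alleles)))

    # leftover pairing has one (donor, patient) pair per mismatch
    expect_identical(nrow(rec$pairing), rec$count)

    # bidirectional iff both vectors non-empty
    expect_identical(
      rec$direction == "bidirectional",
      length(rec$unmatched_patient_alleles) > 0 &&
        length(rec$unmatched_donor_alleles) > 0
    )

    # swapping subjects swaps GvH and HvG and preserves the count
    swp <- locus_mismatch(d, p)
    expect_identical(swp$count, rec$count)
    expect_identical(swp$unmatched_patient_alleles,
                     rec$unmatched_donor_alleles)
    expect_identical(swp$unmatched_donor_alleles,
                     rec$unmatched_patient_alleles)

    # a unidirectional single mismatch requires homozygosity on one side
    if (rec$count == 1 && rec$direction %in% c("GvH", "HvG")) {
      expect_true(p$effectively_homozygous || d$effectively_homozygous)
    }
  }
})

test_that("direction vectors follow allele-type presence", {
  # homozygous patient vs heterozygous donor: HvG only
  p <- normalize_genotype("A", "A*01:01", "A*01:01")
  d <- normalize_genotype("A", "A*01:01", "A*02:01")
  rec <- locus_mismatch(p, d)
  expect_identical(rec$count, 1L)
  expect_identical(rec$direction, "HvG")
  expect_identical(rec$unmatched_donor_alleles, "A*02:01")
  expect_length(rec$unmatched_patient_alleles, 0)

  # one shared, one unshared allele each: bidirectional with paired alleles
  p <- normalize_genotype("C", "C*03:03", "C*07:01")
  d <- normalize_genotype("C", "C*03:04", "C*07:01")
  rec <- locus_mismatch(p, d)
  expect_identical(rec$count, 1L)
  expect_identical(rec$direction, "bidirectional")
  expect_identical(rec$pairing$donor, "C*03:04")
  expect_identical(rec$pairing$patient, "C*03:03")

  # identical genotypes: no mismatch
  p <- normalize_genotype("B", "B*07:02", "B*08:01")
  rec <- locus_mismatch(p, p)
  expect_identical(rec$count, 0L)
  expect_identical(rec$direction, "none")
})

test_that("resolution separates allelic from antigenic mismatches", {
  res <- function(pa, pb, da, db, locus = "C") {
    classify_resolution(locus_mismatch(
      normalize_genotype(locus, pa, pb), normalize_genotype(locus, da, db)
    ))
  }
  expect_equal(res("C*03:03", "C*07:01", "C*03:04", "C*07:01"), "allelic")
  expect_equal(res("A*01:01", "A*03:01", "A*02:01", "A*03:01", "A"),
               "antigenic")
  expect_equal(res("B*35:01", "B*07:02", "B*35:02", "B*07:02", "B"),
               "allelic")
  expect_error(res("C*03:03", "C*07:01", "C*03:03", "C*07:01"),
               "single mismatches")
})

test_that("match grades combine locus counts, class and DPB1 status", {
  gl <- function(locus, a, b) normalize_genotype(locus, a, b)
  patient <- list(
    A = gl("A", "A*01:01", "A*02:01"), B = gl("B", "B*07:02", "B*08:01"),
    C = gl("C", "C*07:01", "C*07:02"),
    DRB1 = gl("DRB1", "DRB1*03:01", "DRB1*15:01"),
    DQB1 = gl("DQB1", "DQB1*02:01", "DQB1*06:02"),
    DPB1 = gl("DPB1", "DPB1*04:01", "DPB1*02:01")
  )
  # fully identical: 10/10 and 12/12
  g <- match_grade(patient, patient)
  expect_identical(g$grade10, 10L)
  expect_identical(g$grade12, 12L)
  expect_equal(as.character(g$category), "10/10")
  expect_equal(g$mm_class, "none")

  # single C mismatch plus double DPB1 mismatch: 9/10, 9/12
  donor <- patient
  donor$C <- gl("C", "C*03:03", "C*07:02")
  donor$DPB1 <- gl("DPB1", "DPB1*03:01", "DPB1*05:01")
  g <- match_grade(patient, donor)
  expect_identical(g$grade10, 9L)
  expect_identical(g$grade12, 9L)
  expect_equal(as.character(g$category), "9/10")
  expect_equal(g$dpb1_status, "double mismatch")
  expect_equal(g$mm_class, "class I")

  # one A and one DQB1 mismatch: 8/10, mixed class, two loci
  donor <- patient
  donor$A <- gl("A", "A*01:01", "A*03:01")
  donor$DQB1 <- gl("DQB1", "DQB1*02:01", "DQB1*03:01")
  g <- match_grade(patient, donor)
  expect_identical(g$grade10, 8L)
  expect_equal(as.character(g$category), "8/10")
  expect_equal(g$mm_class, "mixed")
  expect_identical(g$n_mm_loci, 2L)
})

test_that("grade partition conserves mismatch counts on a synthetic cohort", {
  ann <- shared_annotated()
  total_mm <- ann$mm_a + ann$mm_b + ann$mm_c + ann$mm_drb1 + ann$mm_dqb1
  expect_true(all(ann$grade10 + total_mm == 10L))
  expect_false(any(is.na(ann$category)))
  expect_identical(sum(matching_category_table(ann)$n), nrow(ann))
})

test_that("transplant eras bucket years and reject out-of-range ones", {
  expect_equal(as.character(era_of(c(2009, 2011, 2015, 2016, 2020, 2021))),
               c("pre-2011", "2011-2015", "2011-2015", "2016-2020",
                 "2016-2020", "2021-2022"))
  expect_true(is.na(era_of(NA_integer_)))
  expect_error(era_of(2023), "range")
})
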