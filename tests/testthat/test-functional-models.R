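lg <- function(locus, a, b) normalize_genotype(locus, a, b)

test_that("ARD matching follows P-group identity of the mismatched alleles", {
  ref <- test_reference()
  rec <- locus_mismatch(lg("DRB1", "DRB1*14:01", "DRB1*03:01"),
                        lg("DRB1", "DRB1*14:54", "DRB1*03:01"))
  expect_equal(ard_match(rec, ref), "matched") # both in 14:01P

  rec <- locus_mismatch(lg("A", "A*01:01", "A*03:01"),
                        lg("A", "A*02:01", "A*03:01"))
  expect_equal(ard_match(rec, ref), "mismatched")

  # C*03:03 vs C*03:04: distinct P-groups (ARD mismatched) yet PBM matched,
  # so ARD matching is strictly finer than PBM matching
  p <- lg("C", "C*03:03", "C*07:01")
  d <- lg("C", "C*03:04", "C*07:01")
  rec <- locus_mismatch(p, d)
  expect_equal(ard_match(rec, ref), "mismatched")
  expect_equal(pbm_gvh_match(p, d, ref), "matched")

  expect_error(ard_match(locus_mismatch(p, p), ref), "count >= 1")
})

test_that("PBM-GvH matching covers patient allotypes and propagates NA", {
  ref <- test_reference()
  # mismatched patient allotype in a group absent from the donor
  p <- lg("A", "A*01:01", "A*03:01")
  d <- lg("A", "A*02:01", "A*03:01")
  expect_equal(pbm_gvh_match(p, d, ref), "mismatched")

  # allotype without a PBM assignment -> NA
  p <- lg("A", "A*36:01", "A*03:01")
  d <- lg("A", "A*02:01", "A*03:01")
  expect_true(is.na(pbm_gvh_match(p, d, ref)))

  # same PBM group on the mismatched pair -> matched
  p <- lg("A", "A*01:01", "A*03:01")
  d <- lg("A", "A*26:01", "A*03:01")
  expect_equal(pbm_gvh_match(p, d, ref), "matched")

  # usage errors: DQB1 or matched genotypes
  expect_error(
    pbm_gvh_match(lg("DQB1", "DQB1*02:01", "DQB1*03:01"),
                  lg("DQB1", "DQB1*02:02", "DQB1*03:01"), ref),
    "DRB1"
  )
  expect_error(pbm_gvh_match(p, p, ref), "single-mismatch")
})

test_that("B-leader classification reports verdict and -21 genotype string", {
  ref <- test_reference()
  # shared T allele, both mismatched alleles T -> matched, "TTT"
  out <- b_leader_classify(lg("B", "B*57:01", "B*44:02"),
                           lg("B", "B*58:01", "B*44:02"), ref)
  expect_equal(out$verdict, "matched")
  expect_equal(out$genotype, "TTT")

  # M vs T mismatched alleles
  out <- b_leader_classify(lg("B", "B*07:02", "B*44:02"),
                           lg("B", "B*44:03", "B*44:02"), ref)
  expect_equal(out$verdict, "mismatched")
  expect_equal(out$genotype, "TMT")

  # allele absent from the leader table -> NA
  out <- b_leader_classify(lg("B", "B*15:02", "B*44:02"),
                           lg("B", "B*44:03", "B*44:02"), ref)
  expect_true(is.na(out$verdict))

  expect_error(
    b_leader_classify(lg("B", "B*07:02", "B*08:01"),
                      lg("B", "B*07:02", "B*08:01"), ref),
    "single-B-mismatch"
  )
})

test_that("TCE classification agrees with a brute-force min-group oracle", {
  ref <- test_reference()
  fixture <- c("DPB1*09:01", "DPB1*03:01", "DPB1*14:01",
               "DPB1*04:01", "DPB1*02:01", "DPB1*05:01")
  grp <- c(1, 2, 2, 3, 3, 3)
  names(grp) <- fixture
  oracle <- function(p, d) {
    if (identical(sort(p), sort(d))) {
      return("allele-matched")
    }
    mp <- min(grp[p]); md <- min(grp[d])
    if (mp == md) "permissive"
    else if (mp < md) "non-permissive GvH" else "non-permissive HvG"
  }
  combos <- expand.grid(p1 = fixture, p2 = fixture, d1 = fixture,
                        d2 = fixture, stringsAsFactors = FALSE)
  expect_identical(nrow(combos), 1296L)
  for (i in seq_len(nrow(combos))) {
    p <- lg("DPB1", combos$p1[i], combos$p2[i])
    d <- lg("DPB1", combos$d1[i], combos$d2[i])
    got <- tce_classify(p, d, ref)
    expect_identical(got, oracle(c(p$allele_a, p$allele_b),
                                 c(d$allele_a, d$allele_b)))
    # anti-symmetry: swapping subjects swaps GvH and HvG
    swp <- tce_classify(d, p, ref)
    expected_swp <- c("allele-matched" = "allele-matched",
                      "permissive" = "permissive",
                      "non-permissive GvH" = "non-permissive HvG",
                      "non-permissive HvG" = "non-permissive GvH")[got]
    expect_identical(swp, unname(expected_swp))
  }

  # unknown group propagates
  expect_equal(
    tce_classify(lg("DPB1", "DPB1*99:01", "DPB1*04:01"),
                 lg("DPB1", "DPB1*02:01", "DPB1*04:01"), ref),
    "unknown"
  )
})

test_that("core/non-core subclassification assigns direction or residual", {
  ref <- test_reference()
  sub <- function(pa, pb, da, db) {
    tce_core_subclassify(lg("DPB1", pa, pb), lg("DPB1", da, db), ref)
  }
  # both mismatched alleles core TCE3
  expect_equal(sub("DPB1*02:01", "DPB1*04:01", "DPB1*04:02", "DPB1*04:01"),
               "core")
  # patient's mismatched allele non-core, donor's core: the graft sees it
  expect_equal(sub("DPB1*05:01", "DPB1*04:01", "DPB1*02:01", "DPB1*04:01"),
               "non-core GvH")
  expect_equal(sub("DPB1*02:01", "DPB1*04:01", "DPB1*05:01", "DPB1*04:01"),
               "non-core HvG")
  # non-core on both sides: residual
  expect_equal(sub("DPB1*05:01", "DPB1*04:01", "DPB1*11:01", "DPB1*04:01"),
               "other")
  # permissive but not TCE3-vs-TCE3 (group 2 mismatched alleles): residual
  expect_equal(sub("DPB1*03:01", "DPB1*04:01", "DPB1*14:01", "DPB1*04:01"),
               "other")
  # usage error on non-permissive pairs
  expect_error(sub("DPB1*09:01", "DPB1*04:01", "DPB1*04:02", "DPB1*04:01"),
               "permissive")
})

test_that("expression model applies to single GvH DPB1 mismatches only", {
  ref <- test_reference()
  ec <- function(pa, pb, da, db) {
    expression_classify(lg("DPB1", pa, pb), lg("DPB1", da, db), ref)
  }
  # patient's mismatched allele G-linked -> high
  expect_equal(ec("DPB1*03:01", "DPB1*04:01", "DPB1*02:01", "DPB1*04:01"),
               "high")
  # A-linked -> low
  expect_equal(ec("DPB1*02:01", "DPB1*04:01", "DPB1*03:01", "DPB1*04:01"),
               "low")
  # allele-matched pair -> NA
  expect_true(is.na(ec("DPB1*04:01", "DPB1*02:01",
                       "DPB1*04:01", "DPB1*02:01")))
  # double mismatch -> NA (model not applicable)
  expect_true(is.na(ec("DPB1*03:01", "DPB1*05:01",
                       "DPB1*02:01", "DPB1*04:01")))
  # HvG-only single mismatch (homozygous patient) -> NA
  expect_true(is.na(ec("DPB1*04:01", "DPB1*04:01",
                       "DPB1*03:01", "DPB1*04:01")))
})

test_that("TPHE combines permissiveness and high expression", {
  expect_equal(tphe_classify("permissive", "high"), "TPHE")
  expect_equal(tphe_classify("permissive", "low"), "other")
  expect_equal(tphe_classify("non-permissive GvH", "high"), "other")
  expect_true(is.na(tphe_classify("unknown", "high")))
  expect_true(is.na(tphe_classify("permissive", NA_character_)))
})

test_that("cohort annotation satisfies the cross-model invariants", {
  ann <- shared_annotated()

  # ARD matched implies PBM-GvH matched whenever both are defined
  both <- !is.na(ann$ard) & !is.na(ann$pbm_gvh)
  expect_gt(sum(both & ann$ard == "matched"), 0)
  expect_true(all(ann$pbm_gvh[both & ann$ard == "matched"] == "matched"))

  # TPHE implies permissive and high expression
  tphe <- !is.na(ann$tphe) & ann$tphe == "TPHE"
  expect_gt(sum(tphe), 0)
  expect_true(all(ann$tce[tphe] == "permissive"))
  expect_true(all(ann$dpb1_expression[tphe] == "high"))

  # every pair receives exactly one TCE subset; the partition conserves n
  expect_false(any(is.na(ann$tce_subset)))
  expect_identical(sum(tce_directional_table(ann)$n), nrow(ann))
})
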