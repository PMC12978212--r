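test_that("haplotype pools validate and normalise frequencies", {
  pools <- preset_pools()
  for (p in pools) {
    expect_s3_class(p, "haplotype_pool")
    expect_equal(sum(p$freq), 1)
    expect_true(all(p$freq > 0))
  }
  expect_error(haplotype_pool(tibble::tibble()), "columns")
  bad <- pools[["uniform"]]
  bad$weight[1] <- -1
  expect_error(haplotype_pool(bad), "positive")
})

test_that("every preset allele is covered by the applicable model tables", {
  ref <- test_reference()
  for (pool in preset_pools()) {
    expect_true(all(pool$dpb1 %in% names(ref$tce_group)))
    expect_true(all(pool$dpb1 %in% names(ref$expression)))
    expect_true(all(pool$b %in% names(ref$leader)))
    for (l in c("a", "b", "c", "drb1")) {
      expect_true(all(pool[[l]] %in% names(ref$pbm_group)))
    }
    # TCE3 alleles in the pools have a core/non-core assignment
    tce3 <- pool$dpb1[ref$tce_group[pool$dpb1] == "3"]
    expect_true(all(tce3 %in% names(ref$core_tce3)))
  }
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  a <- sample_cohort(200, registry_size = 10, seed = 7)
  b <- sample_cohort(200, registry_size = 10, seed = 7)
  expect_identical(a, b)
  c <- sample_cohort(200, registry_size = 10, seed = 8)
  expect_false(identical(a, c))
})

test_that("random selection matches the closed-form 10/10 probability", {
  # 4 equifrequent haplotypes with distinct alleles at every locus:
  # P(two random genotypes agree at all five main loci)
  #   = sum_g P(genotype g)^2 = 4*(1/16)^2 + 6*(2/16)^2 = 28/256
  pool <- preset_pools()[["uniform"]]
  cohort <- sample_cohort(3000, pool = pool, selection = "random", seed = 12)
  ann <- annotate_quiet(cohort)
  expect_equal(mean(ann$grade10 == 10L), 28 / 256, tolerance = 0.2)
})

test_that("the 10/10 fraction rises with registry size under best-grade", {
  frac <- vapply(c(1, 25, 250), function(R) {
    cohort <- sample_cohort(800, registry_size = R, seed = 55,
                            selection = if (R == 1) "random" else "best-grade")
    ann <- annotate_quiet(cohort)
    mean(ann$grade10 == 10L)
  }, numeric(1))
  expect_lt(frac[1] + 0.05, frac[2])
  expect_lt(frac[2] + 0.05, frac[3])
})

test_that("grade-threshold selection stops at the first acceptable donor", {
  cohort <- sample_cohort(400, registry_size = 100, seed = 9,
                          selection = "grade-threshold", grade_threshold = 9)
  ann <- annotate_quiet(cohort)
  # acceptable (>= 9/10) donors dominate, but perfect matches are rarer
  # than under best-grade because the search stops early
  best <- annotate_quiet(sample_cohort(400, registry_size = 100, seed = 9))
  expect_gt(mean(ann$grade10 >= 9L), 0.5)
  expect_lt(mean(ann$grade10 == 10L), mean(best$grade10 == 10L))
})

test_that("the dpb1-skewed pool concentrates mismatches on common alleles", {
  common <- paste0("DPB1*", c("01:01", "02:01", "03:01", "04:01", "04:02",
                              "05:01"))
  cohort <- sample_cohort(1500, pool = preset_pools()[["dpb1-skewed"]],
                          registry_size = 50, seed = 31)
  ann <- annotate_quiet(cohort)
  single <- ann$mm_dpb1 == 1L
  slots <- c(ann$du_dpb1[single], ann$pu_dpb1[single])
  expect_gt(mean(slots %in% common), 0.5)
})

test_that("representation ratios are near 1 without donor selection", {
  cohort <- sample_cohort(3000, pool = preset_pools()[["uniform"]],
                          selection = "random", seed = 12)
  ann <- annotate_quiet(cohort)
  rr <- representation_ratio(ann, "A", pairs = "all-mismatched")
  expect_true(all(abs(rr$ratio - 1) < 0.15))
})

test_that("best-match selection depletes common alleles among mismatches", {
  cohort <- sample_cohort(3000, seed = 11)
  ann <- annotate_quiet(cohort)
  rr <- representation_ratio(ann, "A", pairs = "all-mismatched")
  rr <- rr[order(-rr$freq_cohort), ]
  # the two most common A alleles are underrepresented ...
  expect_true(all(rr$ratio[1:2] < 1))
  # ... and the rarest alleles overrepresented
  expect_true(any(utils::tail(rr$ratio, 3) > 1))
})

test_that("time-to-transplant medians recover the configured model", {
  cohort <- sample_cohort(2000, seed = 77)
  ann <- annotate_quiet(cohort)
  tm <- default_time_model()
  obs <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(ann, matching = dplyr::if_else(grade10 == 10L,
                                                   "10/10", "<10/10")),
      era, matching
    ),
    n = dplyr::n(), med = stats::median(months_dx_to_tx), .groups = "drop"
  )
  obs <- dplyr::inner_join(obs, tm, by = c("era" = "era",
                                           "matching" = "matching"))
  big <- obs[obs$n >= 100, ]
  expect_gt(nrow(big), 2)
  expect_true(all(abs(big$med - big$median_months) < 2.5))
})

test_that("mismatch landscapes concentrate when haplotype diversity is low", {
  # one common background whose DRB1 varies between two alleles only, while
  # A varies across six alleles: the DRB1 landscape must have lower entropy
  a_alleles <- c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02",
                 "A*26:01")
  hap <- tibble::tibble(
    a = rep(a_alleles, 2),
    b = "B*07:02", c = "C*07:01",
    drb1 = rep(c("DRB1*14:01", "DRB1*14:54"), each = 6),
    dqb1 = "DQB1*06:02", dpb1 = "DPB1*04:01",
    weight = 1
  )
  pool <- haplotype_pool(hap)
  cohort <- sample_cohort(2500, pool = pool, registry_size = 5, seed = 13)
  ann <- annotate_quiet(cohort)
  e_a <- combination_entropy(mismatch_combination_table(ann, "A"))
  e_drb1 <- combination_entropy(mismatch_combination_table(ann, "DRB1"))
  expect_lt(e_drb1, e_a)
})
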