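# Registry-like synthetic cohorts.  Patients are two haplotypes drawn from
# a 6-locus haplotype pool (so linkage disequilibrium between loci is
# carried by the haplotypes; parental haplotypes are independent, i.e.
# Hardy-Weinberg at the haplotype level).  Donors are selected among
# `registry_size` independently drawn registry genotypes from the same
# pool, by default the best 10/10 grade (ties to the first candidate, which
# is seed-deterministic).  Transplant year follows configurable era
# weights; PTCy adoption and the diagnosis-to-transplant time distribution
# (log-normal, matching-status and era dependent) are era-stratified.

#' Construct a haplotype pool
#'
#' @param haplotypes A tibble/data frame with columns `a`, `b`, `c`,
#'   `drb1`, `dqb1`, `dpb1` (allele names) and `weight` (positive relative
#'   frequencies; normalised to sum to 1).
#' @return A tibble of class `haplotype_pool` with a `freq` column.
#' @export
haplotype_pool <- function(haplotypes) {
  haplotypes <- as_tibble(haplotypes)
  need <- c(tolower(HLA_LOCI), "weight")
  if (!all(need %in% names(haplotypes))) {
    abort(paste0("Haplotype pool needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(haplotypes) == 0) abort("Haplotype pool is empty")
  if (any(!is.finite(haplotypes$weight) | haplotypes$weight <= 0)) {
    abort("Haplotype weights must be positive")
  }
  for (l in tolower(HLA_LOCI)) {
    p <- parse_allele(haplotypes[[l]])
    if (any(p$locus != toupper(l))) {
      abort(sprintf("Column '%s' contains alleles at the wrong locus", l))
    }
    haplotypes[[l]] <- allele_key(p)
  }
  haplotypes$freq <- haplotypes$weight / sum(haplotypes$weight)
  structure(haplotypes, class = c("haplotype_pool", class(haplotypes)))
}

#' Curated haplotype pool presets
#'
#' Three small pools: `"euro-toy"`, a 32-haplotype caricature of common
#' European haplotypes with linkage disequilibrium and near-miss
#' single-locus variants (including the classic mismatch partners
#' DRB1*14:01/14:54, C*03:03/03:04 and the B*35 family);
#' `"uniform"`, four equifrequent haplotypes with distinct alleles
#' at every locus (useful for closed-form checks and selection-off nulls);
#' and `"dpb1-skewed"`, the euro-toy pool with DPB1 mass concentrated on
#' the six very common alleles DPB1*01:01/02:01/03:01/04:01/04:02/05:01.
#' Every allele in the presets is covered by the packaged model tables.
#'
#' @return A named list of [haplotype_pool()] objects.
#' @export
preset_pools <- function() {
  # Common 5-locus backgrounds, several with single-locus allelic variants
  # (near-miss haplotypes drive 9/10 matches and the skewed class II
  # mismatch landscape), and DPB1 variation within backgrounds (weak DPB1
  # linkage drives DPB1 mismatch among otherwise 10/10-matched pairs).
  euro <- tibble::tribble(
    ~a, ~b, ~c, ~drb1, ~dqb1, ~dpb1, ~weight,
    "A*01:01", "B*08:01", "C*07:01", "DRB1*03:01", "DQB1*02:01", "DPB1*04:01", 8,
    "A*01:01", "B*08:01", "C*07:01", "DRB1*03:01", "DQB1*02:01", "DPB1*01:01", 6,
    "A*02:01", "B*07:02", "C*07:02", "DRB1*15:01", "DQB1*06:02", "DPB1*04:01", 7,
    "A*02:01", "B*07:02", "C*07:02", "DRB1*15:01", "DQB1*06:02", "DPB1*04:02", 5,
    "A*03:01", "B*07:02", "C*07:02", "DRB1*15:01", "DQB1*06:02", "DPB1*04:01", 4,
    "A*03:01", "B*07:02", "C*07:02", "DRB1*15:01", "DQB1*06:02", "DPB1*02:01", 3,
    "A*02:01", "B*44:02", "C*05:01", "DRB1*04:01", "DQB1*03:01", "DPB1*04:01", 4,
    "A*02:01", "B*44:02", "C*05:01", "DRB1*04:01", "DQB1*03:01", "DPB1*03:01", 4,
    "A*02:01", "B*44:02", "C*05:01", "DRB1*04:04", "DQB1*03:01", "DPB1*04:01", 3,
    "A*02:01", "B*44:02", "C*05:01", "DRB1*04:01", "DQB1*03:02", "DPB1*02:01", 2,
    "A*02:01", "B*15:01", "C*03:03", "DRB1*04:01", "DQB1*03:02", "DPB1*04:02", 5,
    "A*02:01", "B*15:01", "C*03:04", "DRB1*04:01", "DQB1*03:02", "DPB1*02:01", 4,
    "A*11:01", "B*35:01", "C*04:01", "DRB1*01:01", "DQB1*05:01", "DPB1*04:02", 3,
    "A*11:01", "B*35:01", "C*04:01", "DRB1*01:01", "DQB1*05:01", "DPB1*05:01", 2,
    "A*11:01", "B*35:02", "C*04:01", "DRB1*01:01", "DQB1*05:01", "DPB1*04:02", 2,
    "A*11:01", "B*35:03", "C*04:01", "DRB1*01:01", "DQB1*05:01", "DPB1*05:01", 2,
    "A*29:02", "B*44:03", "C*16:01", "DRB1*07:01", "DQB1*02:02", "DPB1*11:01", 3,
    "A*29:02", "B*44:03", "C*16:01", "DRB1*07:01", "DQB1*02:02", "DPB1*04:01", 3,
    "A*24:02", "B*18:01", "C*07:01", "DRB1*11:01", "DQB1*03:01", "DPB1*02:01", 3,
    "A*24:02", "B*18:01", "C*07:01", "DRB1*11:01", "DQB1*03:01", "DPB1*04:01", 2,
    "A*24:02", "B*18:01", "C*07:01", "DRB1*11:04", "DQB1*03:01", "DPB1*02:01", 2,
    "A*68:01", "B*44:02", "C*07:04", "DRB1*14:01", "DQB1*05:03", "DPB1*05:01", 3,
    "A*68:01", "B*44:02", "C*07:04", "DRB1*14:54", "DQB1*05:03", "DPB1*13:01", 2,
    "A*01:01", "B*57:01", "C*06:02", "DRB1*07:01", "DQB1*03:03", "DPB1*03:01", 4,
    "A*26:01", "B*38:01", "C*12:03", "DRB1*13:02", "DQB1*06:04", "DPB1*04:01", 3,
    "A*02:01", "B*13:02", "C*06:02", "DRB1*07:01", "DQB1*02:02", "DPB1*17:01", 2,
    "A*02:01", "B*13:02", "C*06:02", "DRB1*07:01", "DQB1*02:02", "DPB1*09:01", 1,
    "A*25:01", "B*18:01", "C*12:03", "DRB1*15:01", "DQB1*06:02", "DPB1*03:01", 3,
    "A*23:01", "B*44:03", "C*04:01", "DRB1*07:01", "DQB1*02:02", "DPB1*14:01", 2,
    "A*31:01", "B*51:01", "C*15:02", "DRB1*11:01", "DQB1*03:01", "DPB1*06:01", 3,
    "A*33:01", "B*14:02", "C*08:02", "DRB1*01:02", "DQB1*05:01", "DPB1*10:01", 2,
    "A*32:01", "B*40:01", "C*03:04", "DRB1*13:01", "DQB1*06:03", "DPB1*04:01", 3
  )
  uniform <- tibble::tribble(
    ~a, ~b, ~c, ~drb1, ~dqb1, ~dpb1, ~weight,
    "A*01:01", "B*08:01", "C*07:01", "DRB1*03:01", "DQB1*02:01", "DPB1*01:01", 1,
    "A*02:01", "B*07:02", "C*07:02", "DRB1*15:01", "DQB1*06:02", "DPB1*02:01", 1,
    "A*03:01", "B*44:02", "C*05:01", "DRB1*04:01", "DQB1*03:01", "DPB1*03:01", 1,
    "A*24:02", "B*35:01", "C*04:01", "DRB1*07:01", "DQB1*02:02", "DPB1*04:01", 1
  )
  skew_map <- c(
    "DPB1*13:01" = "DPB1*01:01", "DPB1*17:01" = "DPB1*02:01",
    "DPB1*14:01" = "DPB1*03:01", "DPB1*06:01" = "DPB1*04:01",
    "DPB1*10:01" = "DPB1*05:01"
  )
  skew <- euro
  hit <- skew$dpb1 %in% names(skew_map)
  skew$dpb1[hit] <- unname(skew_map[skew$dpb1[hit]])
  list(
    "euro-toy" = haplotype_pool(euro),
    "uniform" = haplotype_pool(uniform),
    "dpb1-skewed" = haplotype_pool(skew)
  )
}

#' Default era weights, PTCy adoption and time-to-transplant model
#'
#' Era weights follow the registry era mix (9/18/49/24%); PTCy adoption
#' rises across eras to an overall rate near 10%; diagnosis-to-transplant
#' times are log-normal with medians anchored at 11.3 vs 14.9 months
#' (10/10 vs <10/10, earliest era) shrinking to 7.4 vs 8.1 months in the
#' latest era.
#'
#' @return `default_time_model()`: a tibble `era`, `matching`,
#'   `median_months`, `sdlog`.
#' @export
default_time_model <- function() {
  tibble(
    era = rep(ERA_LEVELS, each = 2),
    matching = rep(c("10/10", "<10/10"), 4),
    median_months = c(11.3, 14.9, 9.5, 12.0, 8.0, 9.5, 7.4, 8.1),
    sdlog = 0.6
  )
}

#' @rdname default_time_model
#' @export
default_era_weights <- function() {
  c("pre-2011" = 0.09, "2011-2015" = 0.18, "2016-2020" = 0.49,
    "2021-2022" = 0.24)
}

#' @rdname default_time_model
#' @export
default_ptcy_rates <- function() {
  c("pre-2011" = 0.00, "2011-2015" = 0.02, "2016-2020" = 0.10,
    "2021-2022" = 0.22)
}

era_year_ranges <- list(
  "pre-2011" = 2000:2010, "2011-2015" = 2011:2015,
  "2016-2020" = 2016:2020, "2021-2022" = 2021:2022
)

# matched-allele count over the five main loci between a patient genotype
# (per-locus lists of index vectors, recycled across registry columns) and
# candidate genotypes (per-locus lists of n x R index matrices)
grade10_matrix <- function(pool, ph1, ph2, dh1, dh2) {
  n <- length(ph1[[1]])
  R <- ncol(dh1[[1]])
  g <- matrix(0L, n, R)
  for (l in tolower(MAIN_LOCI)) {
    al <- match(pool[[l]], unique(pool[[l]])) # integer codes, same equalities
    p1 <- al[ph1[[l]]]; p2 <- al[ph2[[l]]]
    d1 <- matrix(al[dh1[[l]]], n, R)
    d2 <- matrix(al[dh2[[l]]], n, R)
    sA <- (p1 == d1) + (p2 == d2)
    sB <- (p1 == d2) + (p2 == d1)
    g <- g + pmax(sA, sB)
  }
  g
}

#' Simulate a registry-like cohort of patient-donor pairs
#'
#' @param n_pairs Number of pairs to generate.
#' @param pool A [haplotype_pool()]; default the `"euro-toy"` preset.
#' @param registry_size Candidate donors drawn per search (default 250).
#' @param selection Donor-selection policy: `"best-grade"` (highest 10/10
#'   grade among candidates), `"random"` (first candidate), or
#'   `"grade-threshold"` (first candidate reaching `grade_threshold`, else
#'   the best).
#' @param grade_threshold Matched-allele threshold for
#'   `"grade-threshold"` selection.
#' @param era_weights,ptcy_rates Named vectors over the four eras.
#' @param time_model Tibble as returned by [default_time_model()].
#' @param ld If `TRUE` (default) haplotypes are drawn intact, carrying the
#'   pool's linkage disequilibrium; if `FALSE` each locus is drawn
#'   independently from the pool's marginal frequencies (LD off).
#' @param seed Optional integer; fixing it makes the output byte-identical.
#' @return A cohort tibble in the dialect consumed by [annotate_cohort()].
#' @examples
#' cohort <- sample_cohort(100, registry_size = 20, seed = 42)
#' @export
sample_cohort <- function(n_pairs,
                          pool = preset_pools()[["euro-toy"]],
                          registry_size = 250,
                          selection = c("best-grade", "random",
                                        "grade-threshold"),
                          grade_threshold = 9,
                          era_weights = default_era_weights(),
                          ptcy_rates = default_ptcy_rates(),
                          time_model = default_time_model(),
                          ld = TRUE,
                          seed = NULL) {
  selection <- match.arg(selection)
  stopifnot(inherits(pool, "haplotype_pool"), n_pairs >= 1)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  H <- nrow(pool)
  R <- if (selection == "random") 1L else as.integer(registry_size)
  loci <- tolower(HLA_LOCI)
  # a "haplotype draw" is a per-locus list of pool-row indices: identical
  # across loci when LD is on, independent when off
  draw <- function(k) {
    if (ld) {
      idx <- sample.int(H, k, replace = TRUE, prob = pool$freq)
      setNames(rep(list(idx), length(loci)), loci)
    } else {
      setNames(lapply(loci, function(l) {
        sample.int(H, k, replace = TRUE, prob = pool$freq)
      }), loci)
    }
  }
  as_mat <- function(h) lapply(h, matrix, nrow = n_pairs, ncol = R)

  ph1 <- draw(n_pairs)
  ph2 <- draw(n_pairs)
  dh1 <- as_mat(draw(n_pairs * R))
  dh2 <- as_mat(draw(n_pairs * R))
  g <- grade10_matrix(pool, ph1, ph2, dh1, dh2)
  j <- switch(
    selection,
    "random" = rep(1L, n_pairs),
    "best-grade" = max.col(g, ties.method = "first"),
    "grade-threshold" = {
      ok <- g >= grade_threshold
      first_ok <- max.col(ok, ties.method = "first")
      ifelse(rowSums(ok) > 0, first_ok, max.col(g, ties.method = "first"))
    }
  )
  pick <- cbind(seq_len(n_pairs), j)
  d1 <- lapply(dh1, function(m) m[pick])
  d2 <- lapply(dh2, function(m) m[pick])
  grade <- g[pick]

  era <- sample(ERA_LEVELS, n_pairs, replace = TRUE,
                prob = era_weights[ERA_LEVELS])
  year <- vapply(era, function(e) {
    yr <- era_year_ranges[[e]]
    yr[sample.int(length(yr), 1)]
  }, integer(1))
  matching <- if_else(grade == 10L, "10/10", "<10/10")
  tm <- time_model
  key <- paste(era, matching)
  tm_key <- paste(tm$era, tm$matching)
  idx <- match(key, tm_key)
  months <- round(rlnorm(n_pairs, meanlog = log(tm$median_months[idx]),
                         sdlog = tm$sdlog[idx]), 1)
  ptcy <- if_else(rbinom(n_pairs, 1, ptcy_rates[era]) == 1, "yes", "no")

  out <- tibble(
    pair_id = sprintf("P%05d", seq_len(n_pairs)),
    year = as.integer(year),
    months_dx_to_tx = months,
    ptcy = ptcy
  )
  for (l in tolower(HLA_LOCI)) {
    al <- pool[[l]]
    out[[paste0("patient_", l, "_1")]] <- al[ph1[[l]]]
    out[[paste0("patient_", l, "_2")]] <- al[ph2[[l]]]
    out[[paste0("donor_", l, "_1")]] <- al[d1[[l]]]
    out[[paste0("donor_", l, "_2")]] <- al[d2[[l]]]
  }
  out
}
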