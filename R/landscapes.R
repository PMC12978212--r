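# Cohort-level frequency analytics: direct-counting allele frequencies,
# mismatch-combination landscapes (frequencies relative to the number of
# pairs mismatched at the locus), representation ratios, and the summary
# tables (matching categories, era-stratified matching, resolution and ARD
# rates, PBM and directional TCE tables).  Percentages are half-up to one
# decimal, the registry table style.

#' Direct-counting allele frequencies
#'
#' Counts alleles over 2N chromosomes per subject (homozygotes contribute
#' two copies).
#'
#' @param cohort An annotated (or raw, already two-field) cohort tibble.
#' @param role `"patient"`, `"donor"` or `"both"`.
#' @param locus One of the six loci.
#' @return A tibble `allele`, `n`, `freq` sorted by decreasing frequency.
#' @export
allele_frequencies <- function(cohort, role = c("patient", "donor", "both"),
                               locus = "A") {
  role <- match.arg(role)
  locus <- toupper(locus)
  stopifnot(locus %in% HLA_LOCI)
  l <- tolower(locus)
  subjects <- if (role == "both") c("patient", "donor") else role
  alleles <- unlist(lapply(subjects, function(s) {
    c(cohort[[paste0(s, "_", l, "_1")]], cohort[[paste0(s, "_", l, "_2")]])
  }))
  alleles <- alleles[!is.na(alleles)]
  tibble(allele = alleles) |>
    count(.data$allele, name = "n") |>
    mutate(freq = .data$n / sum(.data$n)) |>
    arrange(desc(.data$freq))
}

#' Mismatch-combination landscape at one locus
#'
#' For the five main loci, combinations are tallied over 9/10 pairs whose
#' sole main-locus mismatch is at `locus`; for DPB1, over single DPB1
#' mismatches within a match-grade stratum (`"10/10"` or `"9/10"`).
#' Frequencies are relative to the number of pairs mismatched at the locus.
#'
#' @param annotated Output of [annotate_cohort()].
#' @param locus One of the six loci.
#' @param stratum Required for DPB1: `"10/10"` or `"9/10"`.
#' @param ordered If `TRUE` (default) combinations are directional
#'   (donor allele, patient allele), following the landscape-plot convention
#'   of donor alleles on one axis and recipient alleles on the other; if
#'   `FALSE` the two directions of a combination are merged.
#' @return A tibble of class `combination_table` with columns
#'   `donor_allele`, `patient_allele` (or `allele_1`, `allele_2` when
#'   unordered), `n`, `freq`, plus attributes `locus`, `denominator`,
#'   `stratum`, `ordered`.
#' @export
mismatch_combination_table <- function(annotated, locus, stratum = NULL,
                                       ordered = TRUE) {
  locus <- toupper(locus)
  stopifnot(locus %in% HLA_LOCI)
  l <- tolower(locus)
  if (locus == "DPB1") {
    if (is.null(stratum) || !stratum %in% c("10/10", "9/10")) {
      abort("DPB1 landscapes require stratum = \"10/10\" or \"9/10\"")
    }
    rows <- annotated$mm_dpb1 == 1L & annotated$category == stratum
  } else {
    if (!is.null(stratum)) {
      abort("stratum applies only to DPB1 landscapes")
    }
    rows <- annotated$grade10 == 9L &
      !is.na(annotated$single_mm_locus) & annotated$single_mm_locus == locus
  }
  du <- annotated[[paste0("du_", l)]][rows]
  pu <- annotated[[paste0("pu_", l)]][rows]
  den <- sum(rows)
  tab <- if (ordered) {
    tibble(donor_allele = du, patient_allele = pu) |>
      count(.data$donor_allele, .data$patient_allele, name = "n")
  } else {
    tibble(allele_1 = pmin(du, pu), allele_2 = pmax(du, pu)) |>
      count(.data$allele_1, .data$allele_2, name = "n")
  }
  tab <- tab |>
    mutate(freq = if (den > 0) .data$n / den else NA_real_) |>
    arrange(desc(.data$n))
  structure(tab, locus = locus, denominator = den, stratum = stratum,
            ordered = ordered,
            class = c("combination_table", class(tab)))
}

#' Aggregate share of named mismatch combinations
#'
#' Sums the frequency of the listed combinations, ignoring direction.
#'
#' @param tbl A `combination_table`.
#' @param combos A list of length-2 character vectors of allele names.
#' @return The summed frequency.
#' @export
combination_share <- function(tbl, combos) {
  keys <- vapply(combos, function(x) paste(sort(x), collapse = "|"), character(1))
  tk <- if (isTRUE(attr(tbl, "ordered"))) {
    paste(pmin(tbl$donor_allele, tbl$patient_allele),
          pmax(tbl$donor_allele, tbl$patient_allele), sep = "|")
  } else {
    paste(tbl$allele_1, tbl$allele_2, sep = "|")
  }
  sum(tbl$freq[tk %in% keys])
}

#' Shannon entropy of a combination table
#'
#' Lower entropy means the mismatch landscape is concentrated in fewer
#' allele combinations.
#'
#' @param tbl A `combination_table`.
#' @return Entropy in nats.
#' @export
combination_entropy <- function(tbl) {
  p <- tbl$n / sum(tbl$n)
  -sum(p * log(p))
}

#' Representation ratio of an allele among mismatched alleles
#'
#' The frequency of an allele among the mismatched alleles at a locus
#' (both sides of the unmatched pairings in 9/10 single mismatches) divided
#' by its frequency among all cohort subjects. Values below 1 indicate the
#' allele is underrepresented among mismatches, the signature of
#' best-match donor selection acting on common alleles.
#'
#' @param annotated Output of [annotate_cohort()].
#' @param locus One of the five main loci.
#' @param allele Optional character vector of alleles; defaults to every
#'   allele observed in the cohort at the locus.
#' @param pairs `"single-9of10"` (default): mismatched alleles are taken
#'   from 9/10 pairs whose sole mismatch is at `locus`, the landscape
#'   convention; `"all-mismatched"`: every unmatched allele pairing at the
#'   locus across the whole cohort.
#' @return A tibble `allele`, `freq_mismatched`, `freq_cohort`, `ratio`.
#' @export
representation_ratio <- function(annotated, locus, allele = NULL,
                                 pairs = c("single-9of10", "all-mismatched")) {
  locus <- toupper(locus)
  pairs <- match.arg(pairs)
  stopifnot(locus %in% MAIN_LOCI)
  l <- tolower(locus)
  rows <- if (pairs == "single-9of10") {
    annotated$grade10 == 9L &
      !is.na(annotated$single_mm_locus) & annotated$single_mm_locus == locus
  } else {
    annotated[[paste0("mm_", l)]] >= 1L
  }
  mm_alleles <- unlist(stringr::str_split(
    c(annotated[[paste0("du_", l)]][rows],
      annotated[[paste0("pu_", l)]][rows]),
    stringr::fixed("/")
  ))
  mm_alleles <- mm_alleles[!is.na(mm_alleles) & mm_alleles != ""]
  cohort_freq <- allele_frequencies(annotated, "both", locus)
  if (is.null(allele)) allele <- cohort_freq$allele
  fc <- cohort_freq$freq[match(allele, cohort_freq$allele)]
  if (any(is.na(fc) | fc == 0)) {
    abort(sprintf("Allele '%s' has zero cohort frequency at %s",
                  allele[is.na(fc) | fc == 0][1], locus))
  }
  fm <- if (length(mm_alleles) > 0) {
    vapply(allele, function(a) mean(mm_alleles == a), numeric(1))
  } else {
    rep(NA_real_, length(allele))
  }
  tibble(allele = allele, freq_mismatched = unname(fm),
         freq_cohort = unname(fc), ratio = unname(fm / fc))
}

# ---- summary tables -------------------------------------------------------

#' Matching-category counts
#'
#' @param annotated A tibble with a `category` column (10/10, 9/10, 8/10,
#'   <8/10).
#' @return A tibble `category`, `n`, `pct`.
#' @export
matching_category_table <- function(annotated) {
  tibble(category = factor(annotated$category, CATEGORY_LEVELS)) |>
    count(.data$category, .drop = FALSE, name = "n") |>
    mutate(pct = pct(.data$n, sum(.data$n)))
}

#' Era-stratified matching proportions
#'
#' Per transplant era: the proportion of 10/10 and 12/12 matched pairs,
#' DPB1 allele matching (overall and within the 10/10), and 9/10 pairs with
#' a class I or class II mismatch.
#'
#' @param annotated Output of [annotate_cohort()].
#' @return A tibble with one row per era.
#' @export
era_matching_table <- function(annotated) {
  annotated |>
    filter(!is.na(.data$era)) |>
    group_by(era = .data$era) |>
    summarise(
      n = n(),
      pct_10of10 = pct(sum(.data$grade10 == 10L), n()),
      pct_12of12 = pct(sum(.data$grade12 == 12L), n()),
      pct_dpb1_matched = pct(sum(.data$mm_dpb1 == 0L), n()),
      pct_dpb1_matched_in_10of10 = pct(
        sum(.data$mm_dpb1 == 0L & .data$grade10 == 10L),
        sum(.data$grade10 == 10L)
      ),
      pct_9of10_class1 = pct(
        sum(.data$grade10 == 9L & .data$mm_class == "class I"), n()
      ),
      pct_9of10_class2 = pct(
        sum(.data$grade10 == 9L & .data$mm_class == "class II"), n()
      ),
      .groups = "drop"
    )
}

#' Share of 9/10 mismatches per locus
#'
#' @param annotated A tibble with `grade10` and `single_mm_locus` columns.
#' @return A tibble `locus`, `n`, `pct` over the 9/10 pairs.
#' @export
locus_share_table <- function(annotated) {
  x <- annotated |> filter(.data$grade10 == 9L, !is.na(.data$single_mm_locus))
  tibble(locus = factor(x$single_mm_locus, MAIN_LOCI)) |>
    count(.data$locus, .drop = FALSE, name = "n") |>
    mutate(pct = pct(.data$n, sum(.data$n)))
}

rate_rows <- function(x, group, flag_col, flag_value, rate_name) {
  x |>
    group_by(group = {{ group }}) |>
    summarise(
      n_mismatched = n(),
      n_hit = sum(.data[[flag_col]] == flag_value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(!!rate_name := pct(.data$n_hit, .data$n_mismatched))
}

with_class_and_overall <- function(x, annotated9, flag_col, flag_value, rate_name) {
  cls <- annotated9 |>
    mutate(group = if_else(.data$single_mm_locus %in% CLASS1_LOCI,
                           "class I", "class II")) |>
    rate_rows(.data$group, flag_col, flag_value, rate_name)
  overall <- annotated9 |>
    mutate(group = "overall") |>
    rate_rows(.data$group, flag_col, flag_value, rate_name)
  bind_rows(x, cls, overall)
}

#' Low-resolution matching rates among 9/10 single mismatches
#'
#' The proportion of single mismatches matched at the antigen (first-field)
#' level, per locus, per class, and overall.
#'
#' @param annotated Output of [annotate_cohort()].
#' @return A tibble `group`, `n_mismatched`, `n_hit`, `pct_lowres_matched`.
#' @export
resolution_rate_table <- function(annotated) {
  x9 <- annotated |> filter(.data$grade10 == 9L, !is.na(.data$single_mm_locus))
  per_locus <- x9 |>
    mutate(group = .data$single_mm_locus) |>
    rate_rows(.data$group, "resolution", "allelic", "pct_lowres_matched")
  with_class_and_overall(per_locus, x9, "resolution", "allelic",
                         "pct_lowres_matched")
}

#' ARD matching rates among 9/10 single mismatches
#'
#' @param annotated Output of [annotate_cohort()].
#' @return A tibble `group`, `n_mismatched`, `n_hit`, `pct_ard_matched`.
#' @export
ard_rate_table <- function(annotated) {
  x9 <- annotated |> filter(.data$grade10 == 9L, !is.na(.data$single_mm_locus))
  per_locus <- x9 |>
    mutate(group = .data$single_mm_locus) |>
    rate_rows(.data$group, "ard", "matched", "pct_ard_matched")
  with_class_and_overall(per_locus, x9, "ard", "matched", "pct_ard_matched")
}

#' Bidirectional mismatch rates among 9/10 pairs
#'
#' @param annotated Output of [annotate_cohort()].
#' @return A tibble `group`, `n_mismatched`, `n_hit`, `pct_bidirectional`.
#' @export
bidirectional_rate_table <- function(annotated) {
  x9 <- annotated |>
    filter(.data$grade10 == 9L, !is.na(.data$single_mm_locus))
  x9$direction <- vapply(seq_len(nrow(x9)), function(i) {
    x9[[paste0("dir_", tolower(x9$single_mm_locus[i]))]][i]
  }, character(1))
  per_locus <- x9 |>
    mutate(group = .data$single_mm_locus) |>
    rate_rows(.data$group, "direction", "bidirectional", "pct_bidirectional")
  with_class_and_overall(per_locus, x9, "direction", "bidirectional",
                         "pct_bidirectional")
}

#' PBM-GvH matching table among 9/10 single mismatches (Table-3 style)
#'
#' @param annotated A tibble with `grade10`, `single_mm_locus` and `pbm_gvh`
#'   columns (`NA` = assignment not possible).
#' @return A tibble `locus` x `pbm_gvh` (`matched`, `mismatched`, `NA`) with
#'   `n` and `pct` within the locus column.
#' @export
pbm_summary_table <- function(annotated) {
  x <- annotated |>
    filter(.data$grade10 == 9L,
           !is.na(.data$single_mm_locus),
           .data$single_mm_locus %in% c(CLASS1_LOCI, "DRB1")) |>
    mutate(
      locus = factor(.data$single_mm_locus, c(CLASS1_LOCI, "DRB1")),
      pbm_gvh = factor(
        if_else(is.na(.data$pbm_gvh), "NA", .data$pbm_gvh),
        c("matched", "mismatched", "NA")
      )
    )
  x |>
    count(.data$locus, .data$pbm_gvh, .drop = FALSE, name = "n") |>
    group_by(.data$locus) |>
    mutate(pct = pct(.data$n, sum(.data$n))) |>
    ungroup()
}

#' Directional TCE matching table (Table-4 style)
#'
#' Counts and within-category percentages of the directional TCE subsets by
#' match-grade category.
#'
#' @param annotated A tibble with `category` and `tce_subset` columns.
#' @return A tibble `tce_subset` x `category` with `n` and `pct` within
#'   category (pairs with unknown TCE assignment are excluded from the
#'   percentage base and reported as their own row).
#' @export
tce_directional_table <- function(annotated) {
  x <- tibble(
    category = factor(annotated$category, CATEGORY_LEVELS),
    tce_subset = factor(annotated$tce_subset, TCE_SUBSET_LEVELS)
  )
  x |>
    count(.data$category, .data$tce_subset, .drop = FALSE, name = "n") |>
    group_by(.data$category) |>
    mutate(pct = pct(.data$n, sum(.data$n[.data$tce_subset != "unknown"]))) |>
    ungroup()
}

#' Cohort-wide TCE model shares
#'
#' Full-cohort proportions of allele-matched, permissive and non-permissive
#' pairs, the core share among directional (core + non-core) permissive
#' mismatches, and the prevalence of GvH non-core permissive mismatches.
#'
#' @param annotated A tibble with a `tce_subset` column.
#' @return A one-row tibble.
#' @export
tce_overall_shares <- function(annotated) {
  s <- as.character(annotated$tce_subset)
  known <- s != "unknown"
  n <- sum(known)
  permissive <- c("core permissive", "non-core permissive HvG",
                  "non-core permissive GvH", "other permissive")
  directional <- c("core permissive", "non-core permissive HvG",
                   "non-core permissive GvH")
  tibble(
    n = n,
    pct_allele_matched = pct(sum(s == "allele-matched"), n),
    pct_permissive = pct(sum(s %in% permissive), n),
    pct_non_permissive = pct(
      sum(s %in% c("non-permissive HvG", "non-permissive GvH")), n
    ),
    pct_core_of_directional_permissive = pct(
      sum(s == "core permissive"), sum(s %in% directional)
    ),
    pct_gvh_noncore = pct(sum(s == "non-core permissive GvH"), n)
  )
}

#' Summarise an annotated cohort
#'
#' Bundles the landscape summary tables: matching categories, era-stratified
#' matching, per-locus 9/10 shares, low-resolution and ARD rates,
#' bidirectionality, the PBM table, the directional TCE table and cohort
#' TCE shares.
#'
#' @param annotated Output of [annotate_cohort()].
#' @return An object of class `cohort_summary` (a named list of tibbles,
#'   with `n_pairs`). An empty cohort yields zero counts with rates flagged
#'   `NA`.
#' @export
summarize_cohort <- function(annotated) {
  structure(
    list(
      n_pairs = nrow(annotated),
      matching = matching_category_table(annotated),
      era_matching = era_matching_table(annotated),
      locus_shares = locus_share_table(annotated),
      resolution = resolution_rate_table(annotated),
      ard = ard_rate_table(annotated),
      bidirectional = bidirectional_rate_table(annotated),
      pbm = pbm_summary_table(annotated),
      tce = tce_directional_table(annotated),
      tce_overall = tce_overall_shares(annotated)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d pairs>\n\nMatching categories:\n", x$n_pairs))
  print(x$matching)
  cat("\nDirectional TCE table:\n")
  print(tidyr::pivot_wider(x$tce, names_from = "category",
                           values_from = c("n", "pct")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) {
  long <- function(tbl, table_name) {
    tbl |>
      mutate(across(dplyr::where(is.factor), as.character)) |>
      tidyr::pivot_longer(dplyr::where(is.numeric),
                          names_to = "metric", values_to = "value") |>
      tidyr::unite("group", -dplyr::all_of(c("metric", "value")),
                   sep = " / ") |>
      mutate(table = table_name, .before = 1)
  }
  bind_rows(
    long(x$matching, "matching"),
    long(x$era_matching, "era_matching"),
    long(x$locus_shares, "locus_shares"),
    long(x$resolution, "resolution"),
    long(x$ard, "ard"),
    long(x$bidirectional, "bidirectional"),
    long(x$pbm, "pbm"),
    long(x$tce, "tce"),
    long(x$tce_overall |> mutate(group = "cohort"), "tce_overall")
  )
}

#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  m <- x$matching
  tibble(
    n_pairs = x$n_pairs,
    pct_10of10 = m$pct[m$category == "10/10"],
    pct_9of10 = m$pct[m$category == "9/10"],
    pct_mismatched = pct(sum(m$n[m$category != "10/10"]), sum(m$n)),
    pct_allele_matched_dpb1 = x$tce_overall$pct_allele_matched,
    pct_tce_permissive = x$tce_overall$pct_permissive
  )
}
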