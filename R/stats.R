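# Diagnosis-to-transplant time compared between 10/10 and <10/10 matched
# pairs stratified by transplant era: a Kruskal-Wallis omnibus test over the
# era x matching groups followed by Dunn's post hoc z tests on pooled
# mid-ranks with tie-corrected variance.  The default comparison family is
# the four within-era 10/10 vs <10/10 contrasts.

#' Dunn's post hoc test
#'
#' Pairwise z statistics on pooled mid-ranks with the tie-corrected
#' variance,
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie term \eqn{T = \sum_t (t^3 - t) / (12(N-1))}.
#'
#' @param values Numeric vector of observations (NAs dropped).
#' @param groups Group labels, same length.
#' @param contrasts A list of length-2 character vectors naming the group
#'   pairs to test; defaults to all pairs.
#' @param p_adjust Multiplicity adjustment method over the contrast family
#'   (see [stats::p.adjust()]); default `"bonferroni"`.
#' @return A tibble with one row per contrast: `group1`, `group2`, `n1`,
#'   `n2`, `z`, `p_value`, `p_adjusted`. Contrasts with an empty group are
#'   reported with `NA` statistics.
#' @export
dunn_test <- function(values, groups, contrasts = NULL,
                      p_adjust = "bonferroni") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  if (is.null(contrasts)) {
    g <- sort(unique(groups))
    contrasts <- utils::combn(g, 2, simplify = FALSE)
  }
  res <- purrr::map_dfr(contrasts, function(cn) {
    g1 <- cn[1]; g2 <- cn[2]
    n1 <- unname(ns[g1]); n2 <- unname(ns[g2])
    if (is.na(n1) || is.na(n2) || n1 == 0 || n2 == 0) {
      return(tibble(group1 = g1, group2 = g2,
                    n1 = n1 %||% 0L, n2 = n2 %||% 0L,
                    z = NA_real_, p_value = NA_real_))
    }
    z <- (rbar[g1] - rbar[g2]) / sqrt(var_base * (1 / n1 + 1 / n2))
    tibble(group1 = g1, group2 = g2, n1 = n1, n2 = n2,
           z = unname(z), p_value = 2 * pnorm(-abs(unname(z))))
  })
  res$p_adjusted <- pmin(1, p.adjust(res$p_value, method = p_adjust))
  res
}

#' Compare diagnosis-to-transplant time by matching status across eras
#'
#' Pairs are grouped into era x matching status (10/10 vs <10/10) groups; a
#' Kruskal-Wallis test over all non-empty groups is followed by Dunn's test
#' for the four within-era contrasts (the default family), with
#' multiplicity-adjusted p values. Significance is conventionally declared
#' at p < 0.01.
#'
#' @param annotated A tibble with `months_dx_to_tx`, `era` and `category`
#'   (or `grade10`) columns; at least two non-empty groups.
#' @param p_adjust Adjustment method over the contrast family; default
#'   `"bonferroni"` (Dunn's convention).
#' @param family `"within-era"` (default: the four 10/10 vs <10/10
#'   contrasts) or `"all"` (all pairwise).
#' @return An object of class `tx_time_comparison` with the group summary
#'   (n, median, IQR), the omnibus statistic/p and the contrast table; see
#'   [tidy()] and [glance()] methods.
#' @export
compare_time_to_transplant <- function(annotated,
                                       p_adjust = "bonferroni",
                                       family = c("within-era", "all")) {
  family <- match.arg(family)
  matched <- if ("category" %in% names(annotated)) {
    annotated$category == "10/10"
  } else {
    annotated$grade10 == 10L
  }
  x <- tibble(
    months = annotated$months_dx_to_tx,
    era = annotated$era,
    matching = if_else(matched, "10/10", "<10/10")
  ) |>
    filter(!is.na(.data$months), !is.na(.data$era))
  x$group <- paste(x$era, x$matching, sep = " / ")
  if (length(unique(x$group)) < 2) {
    abort("At least two non-empty era x matching groups are required")
  }
  groups_summary <- x |>
    group_by(era = .data$era, matching = .data$matching) |>
    summarise(
      n = n(),
      median = median(.data$months),
      q25 = unname(quantile(.data$months, 0.25)),
      q75 = unname(quantile(.data$months, 0.75)),
      .groups = "drop"
    )
  kw <- kruskal.test(x$months, factor(x$group))
  contrasts <- if (family == "within-era") {
    lapply(levels(droplevels(factor(x$era, ERA_LEVELS))), function(e) {
      paste(e, c("<10/10", "10/10"), sep = " / ")
    })
  } else {
    NULL
  }
  dunn <- dunn_test(x$months, x$group, contrasts = contrasts,
                    p_adjust = p_adjust)
  dunn$era <- stringr::str_remove(dunn$group1, " / .*$")
  structure(
    list(
      groups = groups_summary,
      kruskal_statistic = unname(kw$statistic),
      kruskal_df = unname(kw$parameter),
      kruskal_p = kw$p.value,
      contrasts = dunn,
      p_adjust = p_adjust,
      alpha = 0.01
    ),
    class = "tx_time_comparison"
  )
}

#' @export
print.tx_time_comparison <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis chi-squared = %.2f, df = %d, p = %.3g\n\n",
    x$kruskal_statistic, x$kruskal_df, x$kruskal_p
  ))
  print(x$groups)
  cat(sprintf("\nWithin-era contrasts (Dunn, %s-adjusted):\n", x$p_adjust))
  print(x$contrasts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tx_time_comparison <- function(x, ...) {
  x$contrasts |>
    mutate(significant = !is.na(.data$p_adjusted) &
             .data$p_adjusted < x$alpha)
}

#' @exportS3Method generics::glance
glance.tx_time_comparison <- function(x, ...) {
  tibble(
    statistic = x$kruskal_statistic,
    df = x$kruskal_df,
    p_value = x$kruskal_p,
    n = sum(x$groups$n),
    n_groups = nrow(x$groups)
  )
}
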