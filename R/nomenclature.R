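# WHO HLA nomenclature: "LOCUS*F1:F2[:F3[:F4]][SUFFIX]".  Analysis operates
# at two-field (protein) resolution; higher-resolution names are truncated
# and flagged, one-field names are parsed but flagged as low resolution so
# callers can exclude them from pair annotation.

NULL_SUFFIX <- "N"
EXPRESSION_SUFFIXES <- c("N", "L", "S", "Q", "C", "A")

#' Parse WHO HLA allele names
#'
#' Parses allele strings into their components, reducing names typed at
#' third- or fourth-field resolution to two fields. Locus parsing is
#' case-insensitive; the canonical serialisation is always upper-case
#' `LOCUS*F1:F2` plus any expression suffix.
#'
#' @param x Character vector of allele names, e.g. `"A*01:01"`,
#'   `"C*03:04:01:02"`, `"A*24:09N"`.
#' @param strict If `TRUE` (default) malformed names raise an error naming
#'   the offending token; if `FALSE` they yield a row with `valid = FALSE`
#'   and `NA` fields.
#'
#' @return A tibble with one row per input: `raw`, `locus`, `field1`,
#'   `field2`, `suffix` (`NA` when absent), `n_fields` (fields present in the
#'   input), `truncated` (`TRUE` when fields beyond the second were dropped),
#'   `low_resolution` (`TRUE` for one-field names), `allele` (canonical
#'   two-field serialisation) and `valid`.
#'
#' @examples
#' parse_allele(c("A*01:01", "C*03:04:01:02", "DRB1*14:54"))
#' @export
parse_allele <- function(x, strict = TRUE) {
  stopifnot(is.character(x))
  raw <- x
  x <- stringr::str_trim(x)

  m <- stringr::str_match(
    x,
    "^([A-Za-z0-9]+)\\*([0-9]+)(?::([0-9]+))?(?::([0-9]+))?(?::([0-9]+))?([A-Za-z])?$"
  )
  locus <- toupper(m[, 2])
  f1 <- m[, 3]
  f2 <- m[, 4]
  suffix <- toupper(m[, 7])
  known_locus <- !is.na(locus) & locus %in% HLA_LOCI
  ok_suffix <- is.na(suffix) | suffix %in% EXPRESSION_SUFFIXES
  valid <- !is.na(m[, 1]) & known_locus & ok_suffix

  if (strict && any(!valid)) {
    i <- which(!valid)[1]
    reason <- if (is.na(x[i]) || x[i] == "") {
      c("empty string", raw[i])
    } else if (!stringr::str_detect(x[i], stringr::fixed("*"))) {
      c("no '*' locus separator", x[i])
    } else if (is.na(m[i, 1]) || !is.na(m[i, 1]) && !known_locus[i] &&
               !is.na(locus[i])) {
      if (!is.na(m[i, 1])) {
        c("unknown or unsupported locus", stringr::str_extract(x[i], "^[^*]*"))
      } else {
        c("non-numeric or malformed fields",
          stringr::str_extract(x[i], "(?<=\\*).*"))
      }
    } else {
      c("unknown expression suffix", x[i])
    }
    abort(sprintf("Malformed HLA allele name: %s (offending token: '%s')",
                  reason[1], reason[2]))
  }

  n_fields <- 1L + (!is.na(f2)) + (!is.na(m[, 5])) + (!is.na(m[, 6]))
  n_fields[!valid] <- NA_integer_
  canon <- ifelse(
    is.na(f2), paste0(locus, "*", f1),
    paste0(locus, "*", f1, ":", f2)
  )
  canon <- ifelse(is.na(suffix), canon, paste0(canon, suffix))
  canon[!valid] <- NA_character_

  tibble(
    raw = raw,
    locus = ifelse(valid, locus, NA_character_),
    field1 = ifelse(valid, f1, NA_character_),
    field2 = ifelse(valid, f2, NA_character_),
    suffix = ifelse(valid, suffix, NA_character_),
    n_fields = n_fields,
    truncated = valid & n_fields > 2L,
    low_resolution = valid & n_fields == 1L,
    allele = canon,
    valid = valid
  )
}

# two-field protein-level key used for all matching comparisons (expression
# suffixes other than the null rule do not change matching identity)
allele_key <- function(parsed) {
  ifelse(is.na(parsed$field2), NA_character_,
         paste0(parsed$locus, "*", parsed$field1, ":", parsed$field2))
}

#' Antigen-level (first-field) name of an allele
#'
#' @param x Character vector of allele names (any resolution).
#' @return Character vector of locus-qualified first fields, e.g. `"B*35"`.
#' @examples
#' first_field(c("C*03:03", "C*03:04")) # both "C*03"
#' @export
first_field <- function(x) {
  p <- parse_allele(x)
  paste0(p$locus, "*", p$field1)
}

#' Normalise a single-locus genotype
#'
#' Applies the null-allele rule: a subject carrying a null (`N`-suffixed)
#' allele is considered homozygous for the expressed partner allele at that
#' locus. Alleles are reduced to two-field resolution and sorted so the
#' result is symmetric in its two arguments.
#'
#' @param locus One of `A`, `B`, `C`, `DRB1`, `DQB1`, `DPB1`.
#' @param text_a,text_b Allele strings for the two chromosomes.
#' @return A list of class `locus_genotype`: `locus`, `allele_a`, `allele_b`
#'   (canonical two-field keys, sorted), `effectively_homozygous`, and
#'   `null_replaced` (`TRUE` when the null rule fired).
#' @examples
#' normalize_genotype("A", "A*24:09N", "A*01:01") # homozygous A*01:01
#' @export
normalize_genotype <- function(locus, text_a, text_b) {
  locus <- toupper(locus)
  if (!locus %in% HLA_LOCI) {
    abort(sprintf("Unsupported locus '%s'", locus))
  }
  p <- parse_allele(c(text_a, text_b))
  if (any(p$locus != locus)) {
    abort(sprintf(
      "Allele locus does not match genotype locus '%s' (got '%s')",
      locus, paste(p$raw[p$locus != locus], collapse = "', '")
    ))
  }
  if (any(p$low_resolution)) {
    abort(sprintf(
      "One-field (low-resolution) typing cannot form a genotype: '%s'",
      p$raw[p$low_resolution][1]
    ))
  }
  is_null <- !is.na(p$suffix) & p$suffix == NULL_SUFFIX
  if (all(is_null)) {
    abort(sprintf(
      "Unclassifiable genotype at %s: both alleles are null ('%s', '%s')",
      locus, text_a, text_b
    ))
  }
  keys <- allele_key(p)
  if (any(is_null)) {
    keys <- rep(keys[!is_null], 2)
  }
  keys <- sort(keys)
  structure(
    list(
      locus = locus,
      allele_a = keys[1],
      allele_b = keys[2],
      effectively_homozygous = keys[1] == keys[2],
      null_replaced = any(is_null)
    ),
    class = "locus_genotype"
  )
}

#' @export
print.locus_genotype <- function(x, ...) {
  cat(sprintf(
    "<locus_genotype %s: %s / %s%s%s>\n", x$locus, x$allele_a, x$allele_b,
    if (x$effectively_homozygous) " (homozygous)" else "",
    if (x$null_replaced) " [null rule applied]" else ""
  ))
  invisible(x)
}
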