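# Reference lookup tables behind the functional matching models.
#
# P-groups come from a file in the IPD-IMGT/HLA `hla_nom_p.txt` dialect;
# users can point at the real file (the analysis convention is database
# version 3.53.0) or at the miniature packaged copy.  The five model tables
# (DPB1 TCE groups, core-TCE3 membership, rs9277534-linked expression,
# HLA-B leader -21 residue, PBM groups) ship as TSVs curated from the
# published models; alleles absent from a table yield "unknown", which
# propagates to an NA classification rather than silently defaulting.

#' Load a P-group table from an IPD-IMGT/HLA `hla_nom_p.txt`-dialect file
#'
#' The dialect is line-oriented: comment lines start with `#`; data lines are
#' `LOCUS*;allele1/allele2/...;GROUP` where `GROUP` carries a `P` suffix, or
#' have an empty third field for alleles belonging to no multi-allele group.
#' Allele names are reduced to two fields; only the six supported loci are
#' retained. Alleles absent from any group map to themselves.
#'
#' @param source Path to the file.
#' @return A named character vector of class `p_group_table` mapping
#'   two-field allele keys to P-group identifiers (e.g. `DRB1*14:01` ->
#'   `"DRB1*14:01P"`).
#' @examples
#' pg <- load_p_groups(hlamatchr_example("p_groups_demo.txt"))
#' p_group_of(c("DRB1*14:01", "DRB1*14:54"), pg)
#' @export
load_p_groups <- function(source) {
  lines <- readr::read_lines(source)
  keep <- !stringr::str_starts(lines, "#") & stringr::str_trim(lines) != ""
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- stringr::str_split(lines, stringr::fixed(";"))
  map <- character(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2 || length(p) > 3) {
      abort(sprintf("Malformed P-group line %d: '%s'", lineno[i], lines[i]))
    }
    locus <- toupper(stringr::str_remove(p[1], stringr::fixed("*")))
    if (!locus %in% HLA_LOCI) next
    alleles <- stringr::str_split_1(p[2], stringr::fixed("/"))
    if (any(alleles == "")) {
      abort(sprintf("Malformed P-group line %d: empty allele name", lineno[i]))
    }
    parsed <- tryCatch(
      parse_allele(paste0(locus, "*", alleles)),
      error = function(e) {
        abort(sprintf("Malformed P-group line %d: %s", lineno[i],
                      conditionMessage(e)))
      }
    )
    keys <- unique(allele_key(parsed))
    keys <- keys[!is.na(keys)]
    group <- if (length(p) == 3) stringr::str_trim(p[3]) else ""
    if (group == "") {
      # singleton convention: allele is its own group
      map[keys] <- keys
    } else {
      map[keys] <- paste0(locus, "*", group)
    }
  }
  structure(map, class = "p_group_table")
}

#' P-group of an allele
#'
#' Alleles not listed in the table are their own group (the singleton
#' convention of the format).
#'
#' @param allele Character vector of allele names (reduced to two fields).
#' @param table A `p_group_table` from [load_p_groups()].
#' @return Character vector of P-group identifiers.
#' @export
p_group_of <- function(allele, table) {
  stopifnot(inherits(table, "p_group_table"))
  keys <- allele_key(parse_allele(allele))
  out <- unname(table[keys])
  ifelse(is.na(out), keys, out)
}

model_locus <- list(
  tce_group = "DPB1", core_tce3 = "DPB1", expression = "DPB1",
  leader = "B", pbm_group = c("A", "B", "C", "DRB1")
)

read_model_tsv <- function(path, value_col) {
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"))
  if (!all(c("allele", value_col) %in% names(tab))) {
    abort(sprintf("Model table '%s' must have columns 'allele' and '%s'",
                  path, value_col))
  }
  setNames(tab[[value_col]], allele_key(parse_allele(tab$allele)))
}

#' Assemble the reference tables used by the functional models
#'
#' @param p_groups Path to an `hla_nom_p`-dialect file, or an existing
#'   `p_group_table`.
#' @param tables_dir Directory holding the five model TSVs
#'   (`tce_groups.tsv`, `core_tce3.tsv`, `dpb1_expression.tsv`,
#'   `b_leader.tsv`, `pbm_groups.tsv`), each with columns `allele` and
#'   `verdict`. Defaults to the curated tables shipped with the package.
#' @return A list of class `hla_reference` with elements `p_groups`,
#'   `tce_group`, `core_tce3`, `expression`, `leader`, `pbm_group`.
#' @examples
#' ref <- default_reference()
#' lookup_model("DPB1*09:01", "tce_group", ref)
#' @export
hla_reference <- function(p_groups = hlamatchr_example("p_groups_demo.txt"),
                          tables_dir = system.file("extdata", "model_tables",
                                                   package = "hlamatchr")) {
  pg <- if (inherits(p_groups, "p_group_table")) p_groups else load_p_groups(p_groups)
  ref <- list(
    p_groups = pg,
    tce_group = read_model_tsv(file.path(tables_dir, "tce_groups.tsv"), "verdict"),
    core_tce3 = read_model_tsv(file.path(tables_dir, "core_tce3.tsv"), "verdict"),
    expression = read_model_tsv(file.path(tables_dir, "dpb1_expression.tsv"), "verdict"),
    leader = read_model_tsv(file.path(tables_dir, "b_leader.tsv"), "verdict"),
    pbm_group = read_model_tsv(file.path(tables_dir, "pbm_groups.tsv"), "verdict")
  )
  # locus consistency of every packaged verdict
  for (m in names(model_locus)) {
    loci <- parse_allele(names(ref[[m]]))$locus
    if (!all(loci %in% model_locus[[m]])) {
      abort(sprintf("Model table '%s' contains alleles outside locus set {%s}",
                    m, paste(model_locus[[m]], collapse = ", ")))
    }
  }
  structure(ref, class = "hla_reference")
}

#' @rdname hla_reference
#' @export
default_reference <- function() {
  hla_reference()
}

#' @export
print.hla_reference <- function(x, ...) {
  cat("<hla_reference>\n")
  cat(sprintf("  P-groups: %d alleles, %d groups\n",
              length(x$p_groups), length(unique(x$p_groups))))
  for (m in names(model_locus)) {
    cat(sprintf("  %s: %d alleles\n", m, length(x[[m]])))
  }
  invisible(x)
}

#' Look up a functional-model verdict for an allele
#'
#' @param allele Character vector of allele names.
#' @param model One of `"tce_group"`, `"core_tce3"`, `"expression"`,
#'   `"leader"`, `"pbm_group"`.
#' @param reference An [hla_reference()] object.
#' @return Character vector of verdicts; `NA` (`unknown`) when the allele is
#'   absent from the table. Calling a model on an allele from an invalid
#'   locus is a usage error.
#' @export
lookup_model <- function(allele, model, reference) {
  model <- match.arg(model, names(model_locus))
  parsed <- parse_allele(allele)
  bad <- !parsed$locus %in% model_locus[[model]]
  if (any(bad)) {
    abort(sprintf("Model '%s' is not defined for locus %s (allele '%s')",
                  model, parsed$locus[bad][1], parsed$raw[bad][1]))
  }
  unname(reference[[model]][allele_key(parsed)])
}

#' Path to a packaged example/reference data file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @export
hlamatchr_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "hlamatchr"), recursive = TRUE)
  } else {
    path <- system.file("extdata", file, package = "hlamatchr")
    if (path == "") abort(sprintf("No packaged file '%s'", file))
    path
  }
}
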