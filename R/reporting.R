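# End-to-end orchestration with auditable outputs: every run writes a
# manifest (input hashes, reference versions, options, seed, package
# version) alongside its machine-readable tables, and exclusions are
# reported, never silent.  These functions are the scripted entry points of
# the package; logging goes to standard error via message(), outputs to
# files.

run_manifest <- function(inputs, options) {
  hashes <- vapply(inputs, function(p) {
    if (is.character(p) && length(p) == 1 && file.exists(p)) {
      unname(tools::md5sum(p))
    } else {
      NA_character_
    }
  }, character(1))
  list(
    tool = "hlamatchr",
    version = as.character(utils::packageVersion("hlamatchr")),
    inputs = as.list(inputs),
    input_md5 = as.list(hashes),
    options = options
  )
}

write_manifest <- function(manifest, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Annotate a cohort file and write per-pair records
#'
#' Reads a cohort TSV, annotates it (see [annotate_cohort()]), and writes
#' the per-pair annotation table, an exclusion report and a run manifest to
#' `out_dir`.
#'
#' @param input Path to a cohort TSV.
#' @param out_dir Output directory (created if absent).
#' @param p_groups Path to a P-group file (hla_nom_p dialect); default the
#'   packaged miniature file.
#' @param tables_dir Directory with the five model-table TSVs; default the
#'   packaged curated tables.
#' @param strict Abort on the first unusable row.
#' @return Invisibly, the annotated tibble.
#' @export
run_annotate <- function(input, out_dir,
                         p_groups = hlamatchr_example("p_groups_demo.txt"),
                         tables_dir = system.file("extdata", "model_tables",
                                                  package = "hlamatchr"),
                         strict = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- hla_reference(p_groups = p_groups, tables_dir = tables_dir)
  cohort <- read_cohort(input)
  ann <- annotate_cohort(cohort, ref, strict = strict)
  readr::write_tsv(ann, file.path(out_dir, "annotated.tsv"))
  readr::write_tsv(attr(ann, "exclusions"),
                   file.path(out_dir, "exclusions.tsv"))
  manifest <- run_manifest(
    list(cohort = input, p_groups = p_groups),
    list(strict = strict, n_input = nrow(cohort),
         n_retained = nrow(ann),
         n_excluded = nrow(attr(ann, "exclusions")))
  )
  write_manifest(manifest, out_dir, "annotate")
  message(sprintf("Annotated %d pairs (%d excluded) -> %s",
                  nrow(ann), nrow(attr(ann, "exclusions")), out_dir))
  invisible(ann)
}

#' Summarise an annotated cohort to TSV tables
#'
#' @param annotated An annotated tibble (or path to `annotated.tsv`).
#' @param out_dir Output directory.
#' @return Invisibly, the [summarize_cohort()] object.
#' @export
run_summarize <- function(annotated, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(annotated)) {
    path <- annotated
    annotated <- readr::read_tsv(annotated, show_col_types = FALSE)
    annotated$era <- factor(annotated$era, ERA_LEVELS)
    annotated$category <- factor(annotated$category, CATEGORY_LEVELS)
    annotated$tce_subset <- factor(annotated$tce_subset, TCE_SUBSET_LEVELS)
  } else {
    path <- NA_character_
  }
  s <- summarize_cohort(annotated)
  for (tbl in c("matching", "era_matching", "locus_shares", "resolution",
                "ard", "bidirectional", "pbm", "tce", "tce_overall")) {
    readr::write_tsv(s[[tbl]], file.path(out_dir, paste0(tbl, ".tsv")))
  }
  write_manifest(run_manifest(list(annotated = path),
                              list(n_pairs = s$n_pairs)),
                 out_dir, "summarize")
  message(sprintf("Wrote cohort summary tables for %d pairs -> %s",
                  s$n_pairs, out_dir))
  invisible(s)
}

#' Export a mismatch-combination landscape
#'
#' Writes both the directional (donor, patient) table and the
#' direction-merged view in long format suitable for ribbon/chord plotting.
#'
#' @param annotated An annotated tibble.
#' @param locus Locus of the landscape.
#' @param out_dir Output directory.
#' @param stratum For DPB1: `"10/10"` or `"9/10"`.
#' @return Invisibly, the ordered `combination_table`.
#' @export
run_landscape <- function(annotated, locus, out_dir, stratum = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ordered <- mismatch_combination_table(annotated, locus, stratum = stratum)
  merged <- mismatch_combination_table(annotated, locus, stratum = stratum,
                                       ordered = FALSE)
  tag <- paste0(tolower(locus),
                if (!is.null(stratum)) paste0("_", gsub("/", "of", stratum)))
  readr::write_tsv(ordered, file.path(out_dir, paste0("landscape_", tag, ".tsv")))
  readr::write_tsv(merged,
                   file.path(out_dir, paste0("landscape_", tag, "_merged.tsv")))
  write_manifest(
    run_manifest(list(), list(locus = locus, stratum = stratum,
                              denominator = attr(ordered, "denominator"))),
    out_dir, paste0("landscape_", tag)
  )
  invisible(ordered)
}

#' Simulate a cohort and write it to disk
#'
#' @param out_dir Output directory.
#' @param n_pairs,seed,... Passed to [sample_cohort()].
#' @return Invisibly, the cohort tibble.
#' @export
run_simulate <- function(out_dir, n_pairs, seed, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sample_cohort(n_pairs, seed = seed, ...)
  path <- file.path(out_dir, "cohort.tsv")
  write_cohort(cohort, path)
  write_manifest(run_manifest(list(), list(n_pairs = n_pairs, seed = seed)),
                 out_dir, "simulate")
  message(sprintf("Simulated %d pairs -> %s", n_pairs, path))
  invisible(cohort)
}
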