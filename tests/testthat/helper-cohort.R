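# Shared fixtures, built in code.  The reference tables and the main
# synthetic cohort are cached across test files.

.cache <- new.env(parent = emptyenv())

test_reference <- function() {
  if (is.null(.cache$ref)) .cache$ref <- default_reference()
  .cache$ref
}

# annotated euro-toy cohort under the default study conditions
shared_annotated <- function() {
  if (is.null(.cache$ann)) {
    cohort <- sample_cohort(3000, seed = 101)
    .cache$ann <- suppressMessages(annotate_cohort(cohort, test_reference()))
  }
  .cache$ann
}

base_genotypes <- list(
  a = c("A*01:01", "A*02:01"),
  b = c("B*07:02", "B*08:01"),
  c = c("C*07:01", "C*07:02"),
  drb1 = c("DRB1*03:01", "DRB1*15:01"),
  dqb1 = c("DQB1*02:01", "DQB1*06:02"),
  dpb1 = c("DPB1*04:01", "DPB1*02:01")
)

# one cohort row: both subjects carry the base genotypes unless overridden,
# e.g. make_pair(donor = list(c = c("C*03:04", "C*07:01")))
make_pair <- function(pair_id = "P1", year = 2018, months = 8, ptcy = "no",
                      patient = list(), donor = list()) {
  row <- tibble::tibble(pair_id = pair_id, year = as.integer(year),
                        months_dx_to_tx = months, ptcy = ptcy)
  pg <- utils::modifyList(base_genotypes, patient)
  dg <- utils::modifyList(base_genotypes, donor)
  for (l in names(base_genotypes)) {
    row[[paste0("patient_", l, "_1")]] <- pg[[l]][1]
    row[[paste0("patient_", l, "_2")]] <- pg[[l]][2]
    row[[paste0("donor_", l, "_1")]] <- dg[[l]][1]
    row[[paste0("donor_", l, "_2")]] <- dg[[l]][2]
  }
  row
}

make_cohort <- function(...) dplyr::bind_rows(...)

annotate_quiet <- function(cohort, ...) {
  suppressMessages(annotate_cohort(cohort, test_reference(), ...))
}

pool_alleles <- function(pool, locus) unique(pool[[tolower(locus)]])
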