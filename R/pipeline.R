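## End-to-end convenience wrappers: wells -> QC -> genotypes -> loads, and
## the study's headline comparison (human-DNA load in mutants vs siblings).

#' Run the qPCR load pipeline
#'
#' Chains [qc_filter_well()] (dropping dimer-only wells),
#' [collapse_replicates()], [genotype_cohort()] and [tumor_load_table()].
#'
#' @param wells a wells data frame (from [read_well_table()] or
#'   [simulate_qpcr()]).
#' @param cfg a [qc_config()]; set `amplicon_tm` to enable melting-curve
#'   screening.
#' @param windows a [genotype_windows()].
#' @param curve optional `standard_curve` for absolute pg estimates.
#' @return list with `wells` (QC-annotated), `collapsed`, `genotypes` (a
#'   `genotype_cohort`) and `loads` (from [tumor_load_table()]).
#' @export
run_load_pipeline <- function(wells, cfg = qc_config(),
                              windows = genotype_windows(), curve = NULL) {
  wells <- qc_filter_well(wells, cfg)
  usable <- wells[wells$verdict != "dimer_only", , drop = FALSE]
  collapsed <- collapse_replicates(usable)
  genotypes <- genotype_cohort(collapsed, windows)
  loads <- tumor_load_table(genotypes, collapsed, curve)
  list(wells = wells, collapsed = collapsed, genotypes = genotypes,
       loads = loads)
}

#' Mutant-versus-sibling load comparison
#'
#' One-tailed Student's t-test of the normalized human-DNA load
#' (`load_dct`) in called mutant homozygotes against wild-type/heterozygote
#' siblings, testing for a higher load in mutants (the direction the imaging
#' results establish). Embryos without a numeric load are excluded and
#' counted.
#'
#' @param loads output of [tumor_load_table()].
#' @param tails,direction passed to [t_test()]; defaults are the study's
#'   one-tailed comparison.
#' @return a [test_result()] with attributes `n_mutant`, `n_sibling` and
#'   `n_excluded`.
#' @export
compare_mutant_load <- function(loads, tails = "one", direction = "greater") {
  ok <- !is.na(loads$load_dct)
  mut <- loads$load_dct[ok & loads$genotype == "MUT_HOM"]
  sib <- loads$load_dct[ok & loads$genotype %in% c("WT_HOM", "HET")]
  if (length(mut) < 2 || length(sib) < 2) {
    stop("need >= 2 embryos per arm with a numeric load", call. = FALSE)
  }
  res <- t_test(mut, sib, tails = tails, direction = direction)
  attr(res, "n_mutant") <- length(mut)
  attr(res, "n_sibling") <- length(sib)
  attr(res, "n_excluded") <- sum(!ok)
  res
}

#' Simulate a cohort and test the genotype effect on tumor DNA load
#'
#' Full generator-to-inference round trip used for power and type-I-error
#' studies: simulate a cohort and its qPCR plate, run the load pipeline, and
#' return the one-tailed mutant-vs-sibling test.
#'
#' @param cfg a [sim_config()].
#' @return a [test_result()] from [compare_mutant_load()].
#' @export
pipeline_load_test <- function(cfg) {
  sim <- simulate_cohort(cfg)
  wells <- simulate_qpcr(sim$truth, cfg, sim$samples)
  qc <- qc_config(ct_nondetect_cutoff = cfg$dropout_cutoff,
                  amplicon_tm = cfg$amplicon_tm)
  res <- run_load_pipeline(wells, qc)
  compare_mutant_load(res$loads)
}
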