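## Single-embryo ache genotyping from allele-specific qPCR.
##
## Two primer sets amplify the host ache locus: "S" preferentially amplifies
## the wild-type allele, "N" the sb55 mutant allele. The Ct difference
## delta = Ct(N) - Ct(S) separates the three genotypes of a heterozygote
## in-cross: strongly positive for wild-type homozygotes (the mutant-specific
## primer limps along ~10 cycles late), strongly negative for mutant
## homozygotes, and near zero for heterozygotes where both alleles are
## present in one copy each.

#' Genotype-calling windows on the allele-specific Ct difference
#'
#' The defaults follow the study's rule: absolute Ct differences of at most
#' `het_halfwidth` (1 cycle) are heterozygous, at least `hom_threshold`
#' (4 cycles) homozygous with the sign giving the allele, and anything
#' strictly between is unclassified. Boundary values are assigned to the
#' classified side.
#'
#' @param het_halfwidth half-width (cycles) of the heterozygote window
#'   around zero.
#' @param hom_threshold minimum absolute Ct difference (cycles) for a
#'   homozygote call.
#' @return an object of class `genotype_windows`.
#' @export
genotype_windows <- function(het_halfwidth = 1, hom_threshold = 4) {
  stopifnot(het_halfwidth > 0, hom_threshold > het_halfwidth)
  structure(list(het_halfwidth = het_halfwidth,
                 hom_threshold = hom_threshold),
            class = "genotype_windows")
}

.genotype_levels <- c("WT_HOM", "HET", "MUT_HOM", "UNCLASSIFIED")

#' Call ache genotype from allele-specific Ct values
#'
#' With both Ct values numeric the call is made on
#' `delta_ct_ns = ct_n - ct_s`: `|delta| <= het_halfwidth` is `HET`,
#' `delta >= hom_threshold` is `WT_HOM`, `delta <= -hom_threshold` is
#' `MUT_HOM`, and the band in between is `UNCLASSIFIED`. With exactly one
#' non-detect, the homozygote favored by the detected allele is called
#' (S detected gives `WT_HOM`, N detected gives `MUT_HOM`) and flagged
#' `single_allele_call`, since a failed reaction cannot be distinguished
#' from true allele absence. Both non-detect is an error; such samples must
#' be excluded upstream.
#'
#' @param ct_n Ct of the mutant-specific (N) primer; `NA` for non-detect.
#'   Vectorized.
#' @param ct_s Ct of the wild-type-specific (S) primer; `NA` for non-detect.
#' @param windows a [genotype_windows()].
#' @return data frame with `ct_n`, `ct_s`, `delta_ct_ns`, `call` (factor with
#'   levels `WT_HOM`, `HET`, `MUT_HOM`, `UNCLASSIFIED`) and `flag`.
#' @examples
#' call_genotype(30.00, 20.15)  # delta = +9.85 -> WT_HOM
#' call_genotype(20.00, 25.65)  # delta = -5.65 -> MUT_HOM
#' call_genotype(22.5, 20.0)    # delta in (1, 4) -> UNCLASSIFIED
#' @export
call_genotype <- function(ct_n, ct_s, windows = genotype_windows()) {
  stopifnot(length(ct_n) == length(ct_s))
  if (any(is.na(ct_n) & is.na(ct_s))) {
    stop("no amplification: both allele-specific reactions are non-detect",
         call. = FALSE)
  }
  delta <- ct_n - ct_s
  call <- rep(NA_character_, length(delta))
  flag <- rep("", length(delta))

  both <- !is.na(delta)
  h <- windows$het_halfwidth
  H <- windows$hom_threshold
  call[both & abs(delta) <= h] <- "HET"
  call[both & delta >= H] <- "WT_HOM"
  call[both & delta <= -H] <- "MUT_HOM"
  call[both & is.na(call)] <- "UNCLASSIFIED"

  s_only <- is.na(ct_n) & !is.na(ct_s)
  n_only <- !is.na(ct_n) & is.na(ct_s)
  call[s_only] <- "WT_HOM"
  call[n_only] <- "MUT_HOM"
  flag[s_only | n_only] <- "single_allele_call"

  data.frame(ct_n = ct_n, ct_s = ct_s, delta_ct_ns = delta,
             call = factor(call, levels = .genotype_levels),
             flag = flag, stringsAsFactors = FALSE)
}

#' Genotype a cohort of embryos from collapsed qPCR data
#'
#' Takes the per-(sample, primer) table from [collapse_replicates()], pairs
#' each sample's `ACHE_N` and `ACHE_S` mean Ct values and calls
#' [call_genotype()]. Samples in which both allele-specific reactions failed
#' are retained with an empty call and flag `no_amplification`; unclassified
#' samples are counted separately, never dropped.
#'
#' @param collapsed output of [collapse_replicates()].
#' @param windows a [genotype_windows()].
#' @return an object of class `genotype_cohort`: list with `calls` (one row
#'   per sample: `sample_id`, `ct_n`, `ct_s`, `delta_ct_ns`, `call`, `flag`),
#'   `summary` (named counts per class plus `no_amplification`) and `windows`.
#' @export
genotype_cohort <- function(collapsed, windows = genotype_windows()) {
  stopifnot(is.data.frame(collapsed))
  geno <- collapsed[collapsed$primer_id %in% c("ACHE_N", "ACHE_S"), ,
                    drop = FALSE]
  ids <- sort(unique(geno$sample_id))
  pick <- function(primer) {
    sub <- geno[geno$primer_id == primer, , drop = FALSE]
    ct <- sub$ct_mean[match(ids, sub$sample_id)]
    ct[is.na(ct)] <- NA_real_  # missing row and non-detect group both NA
    ct
  }
  ct_n <- pick("ACHE_N")
  ct_s <- pick("ACHE_S")

  no_amp <- is.na(ct_n) & is.na(ct_s)
  calls <- data.frame(sample_id = ids, ct_n = ct_n, ct_s = ct_s,
                      delta_ct_ns = NA_real_,
                      call = factor(NA_character_,
                                    levels = .genotype_levels),
                      flag = "", stringsAsFactors = FALSE)
  if (any(!no_amp)) {
    sub <- call_genotype(ct_n[!no_amp], ct_s[!no_amp], windows)
    calls$delta_ct_ns[!no_amp] <- sub$delta_ct_ns
    calls$call[!no_amp] <- sub$call
    calls$flag[!no_amp] <- sub$flag
  }
  calls$flag[no_amp] <- "no_amplification"

  counts <- table(calls$call)
  summary <- c(as.vector(counts), sum(no_amp))
  names(summary) <- c(names(counts), "no_amplification")
  structure(list(calls = calls, summary = summary, windows = windows),
            class = "genotype_cohort")
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat("Genotype calls for", nrow(x$calls), "embryos",
      sprintf("(HET window |dCt| <= %g, homozygote threshold %g cycles)\n",
              x$windows$het_halfwidth, x$windows$hom_threshold))
  print(x$summary)
  invisible(x)
}

#' Write a genotype table to CSV
#'
#' @param cohort a `genotype_cohort` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  df <- cohort$calls
  df$call <- as.character(df$call)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
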