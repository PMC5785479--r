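## AluYb8 human-DNA load, qPCR standard curve, and delta-delta-Ct expression.
##
## Human tumor DNA in a xenografted larva is measured by qPCR on the AluYb8
## repeat and normalized against the host's single-copy ache locus. Because
## homozygotes amplify their primary allele from two genomic copies while
## heterozygotes have one copy per allele, the homozygote reference Ct is
## shifted by +1 cycle (one cycle = one doubling) before normalization;
## heterozygotes use the mean of the two allele-specific Ct values.

#' Copy-number-adjusted host reference Ct
#'
#' For a wild-type homozygote, `ct_s + 1`; for a mutant homozygote,
#' `ct_n + 1` (the "+1" represents the 2-fold copy-number difference between
#' a two-copy primary allele and a heterozygote's single-copy alleles); for
#' heterozygotes, the mean of both primers. Unclassified genotypes cannot be
#' normalized.
#'
#' @param call genotype class (`"WT_HOM"`, `"HET"`, `"MUT_HOM"`); vectorized.
#' @param ct_n mutant-specific primer Ct (cycles).
#' @param ct_s wild-type-specific primer Ct (cycles).
#' @return adjusted reference Ct, in cycles.
#' @examples
#' adjusted_reference_ct("WT_HOM", ct_n = 30, ct_s = 20)  # 21
#' adjusted_reference_ct("HET", ct_n = 20, ct_s = 21)     # 20.5
#' @export
adjusted_reference_ct <- function(call, ct_n, ct_s) {
  call <- as.character(call)
  n <- max(length(call), length(ct_n), length(ct_s))
  call <- rep_len(call, n); ct_n <- rep_len(ct_n, n); ct_s <- rep_len(ct_s, n)
  if (any(is.na(call) | !call %in% c("WT_HOM", "HET", "MUT_HOM"))) {
    stop("genotype required before normalization", call. = FALSE)
  }
  needed_na <- (call == "WT_HOM" & is.na(ct_s)) |
    (call == "MUT_HOM" & is.na(ct_n)) |
    (call == "HET" & (is.na(ct_n) | is.na(ct_s)))
  if (any(needed_na)) {
    stop("reference Ct missing for the called genotype", call. = FALSE)
  }
  ifelse(call == "WT_HOM", ct_s + 1,
         ifelse(call == "MUT_HOM", ct_n + 1, (ct_n + ct_s) / 2))
}

#' Normalized human-DNA load (delta Ct)
#'
#' `load_dct = ct_ref_adjusted - ct_alu`, oriented so that a larger value
#' means more human tumor DNA (more template lowers the AluYb8 Ct). This
#' orientation is the package's single sign convention and is recorded in
#' the output of [tumor_load_table()].
#'
#' @param ct_alu AluYb8 Ct (cycles); vectorized.
#' @param ct_ref_adjusted copy-number-adjusted host reference Ct from
#'   [adjusted_reference_ct()].
#' @return normalized load in cycles (host minus human).
#' @examples
#' alu_load(ct_alu = 25, ct_ref_adjusted = 21)  # -4
#' @export
alu_load <- function(ct_alu, ct_ref_adjusted) {
  ct_ref_adjusted - ct_alu
}

#' Per-embryo tumor-load table
#'
#' Pipeline glue joining genotype calls with collapsed AluYb8 Ct values:
#' computes the adjusted reference Ct and normalized load for every embryo
#' with a classified genotype. Embryos whose AluYb8 reaction is a non-detect
#' are kept with flag `below_detection` and an `NA` load so that mean
#' comparisons can report how many were excluded; unclassified genotypes are
#' flagged `unclassified_genotype`.
#'
#' @param cohort a `genotype_cohort` from [genotype_cohort()].
#' @param collapsed output of [collapse_replicates()] containing `ALU_YB8`
#'   rows.
#' @param curve optional [fit_standard_curve()] fit; when supplied,
#'   `est_human_dna_pg` is added via [predict_human_dna()].
#' @return data frame with `sample_id`, `genotype`, `ct_ref_adjusted`,
#'   `ct_alu`, `load_dct` (sign convention: larger = more human DNA),
#'   optional `est_human_dna_pg`, and `flag`.
#' @export
tumor_load_table <- function(cohort, collapsed, curve = NULL) {
  stopifnot(inherits(cohort, "genotype_cohort"), is.data.frame(collapsed))
  calls <- cohort$calls
  alu <- collapsed[collapsed$primer_id == "ALU_YB8", , drop = FALSE]
  ct_alu <- alu$ct_mean[match(calls$sample_id, alu$sample_id)]

  classified <- !is.na(calls$call) & calls$call != "UNCLASSIFIED"
  ct_ref <- rep(NA_real_, nrow(calls))
  ct_ref[classified] <- adjusted_reference_ct(
    as.character(calls$call[classified]),
    calls$ct_n[classified], calls$ct_s[classified])

  load <- ifelse(classified & !is.na(ct_alu), alu_load(ct_alu, ct_ref),
                 NA_real_)
  flag <- ifelse(!classified, "unclassified_genotype",
                 ifelse(is.na(ct_alu), "below_detection", ""))
  out <- data.frame(sample_id = calls$sample_id,
                    genotype = as.character(calls$call),
                    ct_ref_adjusted = ct_ref, ct_alu = ct_alu,
                    load_dct = load, flag = flag, stringsAsFactors = FALSE)
  if (!is.null(curve)) {
    est <- rep(NA_real_, nrow(out))
    ok <- !is.na(out$ct_alu)
    if (any(ok)) {
      pred <- predict_human_dna(curve, out$ct_alu[ok])
      est[ok] <- pred$human_dna_pg
    }
    out$est_human_dna_pg <- est
  }
  attr(out, "load_orientation") <- "host_minus_human (larger = more human DNA)"
  out
}

#' Fit a qPCR standard curve of Ct against log10 human DNA
#'
#' Ordinary least squares of Ct on `log10(human_dna_pg)` over the detected
#' points of a dilution series run against a constant zebrafish DNA
#' background. Amplification efficiency is `10^(-1/slope) - 1` (1.0 for
#' perfect doubling, slope -3.32). The limit of detection is empirical: the
#' smallest input amount whose Ct is numeric and below the non-detect cutoff.
#'
#' @param points data frame with columns `human_dna_pg` (> 0) and `ct`
#'   (`NA` for non-detect).
#' @param cutoff non-detect Ct cutoff in cycles (default 35).
#' @return an object of class `standard_curve`: `slope`, `intercept`, `r`
#'   (Pearson correlation of the fitted pairs), `efficiency`, `lod_pg`,
#'   `n_points`, `valid` (FALSE for a non-negative slope) and the fitted
#'   `data`.
#' @examples
#' pg <- 10^(4:-2)
#' ct <- ifelse(30 - 3.3219 * log10(pg) > 35, NA, 30 - 3.3219 * log10(pg))
#' fit_standard_curve(data.frame(human_dna_pg = pg, ct = ct))
#' @export
fit_standard_curve <- function(points, cutoff = 35) {
  stopifnot(is.data.frame(points),
            all(c("human_dna_pg", "ct") %in% names(points)))
  if (any(points$human_dna_pg <= 0)) {
    stop("human_dna_pg must be positive", call. = FALSE)
  }
  ok <- !is.na(points$ct)
  if (sum(ok) < 3) stop("insufficient curve: need >= 3 detected points",
                        call. = FALSE)
  lp <- log10(points$human_dna_pg[ok])
  ct <- points$ct[ok]
  if (diff(range(lp)) < 2) {
    warning("detected standards span < 2 log10 units", call. = FALSE)
  }
  fit <- lm(ct ~ lp)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r <- cor(lp, ct)
  detected <- ok & points$ct < cutoff
  lod <- if (any(detected)) min(points$human_dna_pg[detected]) else NA_real_
  structure(list(slope = slope, intercept = intercept, r = r,
                 efficiency = 10^(-1 / slope) - 1,
                 lod_pg = lod, n_points = sum(ok),
                 valid = is.finite(slope) && slope < 0,
                 cutoff = cutoff,
                 data = points[ok, c("human_dna_pg", "ct")]),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve: Ct =",
      sprintf("%.4f %+.4f * log10(pg)", x$intercept, x$slope), "\n")
  cat(sprintf("  n = %d points, r = %.4f, efficiency = %.3f, LOD = %g pg%s\n",
              x$n_points, x$r, x$efficiency, x$lod_pg,
              if (x$valid) "" else "  [INVALID: non-negative slope]"))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.standard_curve <- function(x, ...) {
  lp <- log10(x$data$human_dna_pg)
  plot(lp, x$data$ct, xlab = "log10 human DNA (pg)", ylab = "Ct",
       main = "qPCR standard curve", ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Inverse prediction of human DNA amount from a Ct value
#'
#' `pg = 10^((ct - intercept) / slope)` on a valid standard curve. Estimates
#' below the curve's empirical limit of detection are flagged.
#'
#' @param fit a valid `standard_curve`.
#' @param ct Ct values (cycles); vectorized.
#' @return data frame with `ct`, `human_dna_pg` and logical `below_lod`.
#' @export
predict_human_dna <- function(fit, ct) {
  stopifnot(inherits(fit, "standard_curve"))
  if (!fit$valid) stop("invalid standard curve (non-negative slope)",
                       call. = FALSE)
  if (any(is.na(ct))) stop("ct must be numeric", call. = FALSE)
  pg <- 10^((ct - fit$intercept) / fit$slope)
  data.frame(ct = ct, human_dna_pg = pg,
             below_lod = !is.na(fit$lod_pg) & pg < fit$lod_pg)
}

#' @param object a `standard_curve`.
#' @param ct Ct values to invert.
#' @param ... ignored.
#' @rdname predict_human_dna
#' @export
predict.standard_curve <- function(object, ct, ...) {
  predict_human_dna(object, ct)
}

#' Delta-delta-Ct relative expression
#'
#' `ddct = (ct_target - ct_reference) - (calibrator_ct_target -
#' calibrator_ct_reference)`; expression relative to the calibrator is
#' `2^(-ddct)`, i.e. `log2_fold_change = -ddct`. The calibrator is normally
#' the sample with the lowest target expression; it must express the target
#' (a non-detect calibrator target is an error: choose the next-lowest
#' expresser instead).
#'
#' @param ct_target,ct_reference sample Ct values for target and reference
#'   gene (cycles); vectorized over samples.
#' @param calibrator_ct_target,calibrator_ct_reference calibrator Ct values.
#' @param target_gene,reference_gene optional gene labels carried through.
#' @return data frame with `ct_target`, `ct_reference`, `ddct`,
#'   `log2_fold_change` and `fold_change`.
#' @examples
#' ddct_expression(20, 18, 24, 18)$fold_change  # 16
#' @export
ddct_expression <- function(ct_target, ct_reference,
                            calibrator_ct_target, calibrator_ct_reference,
                            target_gene = NA_character_,
                            reference_gene = NA_character_) {
  if (is.na(calibrator_ct_target)) {
    stop("calibrator must express target: pick the next-lowest expresser",
         call. = FALSE)
  }
  if (any(is.na(ct_target) | is.na(ct_reference)) ||
      is.na(calibrator_ct_reference)) {
    stop("all four Ct values must be numeric", call. = FALSE)
  }
  ddct <- (ct_target - ct_reference) -
    (calibrator_ct_target - calibrator_ct_reference)
  data.frame(target_gene = target_gene, reference_gene = reference_gene,
             ct_target = ct_target, ct_reference = ct_reference,
             ddct = ddct, log2_fold_change = -ddct,
             fold_change = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Does DNA concentration predict the host reference Ct?
#'
#' Pearson correlation between `log2(concentration)` and the host (ache)
#' reference Ct across samples — a significantly negative correlation means
#' input amount predicts the host signal, a sanity check on qPCR efficiency.
#'
#' @param concentration DNA concentrations (ng/ul), > 0.
#' @param ct_ref paired host reference Ct values (cycles).
#' @return list with `r`, `p_value`, `n` and `note` (`"concentration
#'   predicts host Ct"` when r is significantly negative at 0.05; `"r
#'   undefined (constant input)"` for degenerate input).
#' @export
concentration_ct_check <- function(concentration, ct_ref) {
  ok <- !is.na(concentration) & !is.na(ct_ref)
  x <- log2(concentration[ok])
  y <- ct_ref[ok]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                note = "r undefined (constant input)"))
  }
  ct <- cor.test(x, y)
  r <- unname(ct$estimate)
  note <- if (r < 0 && ct$p.value < 0.05) "concentration predicts host Ct"
          else ""
  list(r = r, p_value = ct$p.value, n = length(x), note = note)
}

#' Write a tumor-load table to CSV
#'
#' The load sign convention is stored in a `load_orientation` column on
#' every row so the file is self-describing.
#'
#' @param loads output of [tumor_load_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_load_table <- function(loads, path) {
  df <- loads
  df$load_orientation <- attr(loads, "load_orientation") %||% ""
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a standard-curve report as JSON
#'
#' @param fit a `standard_curve`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_curve_report <- function(fit, path) {
  stopifnot(inherits(fit, "standard_curve"))
  rec <- list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
              efficiency = fit$efficiency, lod_pg = fit$lod_pg,
              n_points = fit$n_points, valid = fit$valid)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
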