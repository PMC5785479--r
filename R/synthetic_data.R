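## Synthetic xenograft cohorts with ground truth.
##
## The generator emulates the statistical structure of the study: Mendelian
## 1:2:1 genotypes from a heterozygote in-cross; allele-specific Ct offsets
## (delta Ct(N-S) ~ +9.85 +/- 1.07 for wild-type homozygotes, -5.65 +/- 0.64
## for mutant homozygotes, ~0 for heterozygotes); log-linear AluYb8 Ct in
## human DNA amount with non-detect dropout above the cutoff; a genotype-
## dependent lognormal tumor-load effect; primer-dimer wells with
## out-of-window melting peaks; and larva images with a yolk tumor blob plus
## dispersed tail cells.
##
## The heterozygote allele model makes the "+1" copy-number correction
## exactly unbiased: each single-copy heterozygote allele amplifies one
## cycle later than a homozygote's two-copy primary allele at equal host
## DNA (one cycle = one template doubling).

#' Simulation configuration
#'
#' All stochastic generator functions derive their randomness from
#' `cfg$seed` (sub-streams are fixed deterministic offsets per function and,
#' for images, per embryo), so every observable table is a pure function of
#' the configuration.
#'
#' @param seed integer seed governing all randomness (mandatory).
#' @param n_embryos cohort size.
#' @param genotype_probs Mendelian class probabilities
#'   `(WT_HOM, HET, MUT_HOM)`; the in-cross default is `(0.25, 0.5, 0.25)`.
#' @param load_median_pg median engrafted human-DNA load (pg) in non-mutant
#'   embryos.
#' @param load_sigma_log lognormal sdlog of the load.
#' @param load_fold_mutant fold increase of the mutant median load (default
#'   2.5, within the reported "up to 3-fold" tumor-size range).
#' @param engraft_rate probability an injected embryo develops a tumor;
#'   non-engrafted embryos keep only a trace (`residual_frac`) of the
#'   injected DNA and show no image signal.
#' @param residual_frac residual DNA fraction in non-engrafted embryos.
#' @param curve_slope,curve_intercept AluYb8 calibration: `Ct =
#'   intercept + slope * log10(pg)`. The defaults (-3.3219, 30) put the last
#'   detected ten-fold standard at 0.1 pg under the 35-cycle cutoff.
#' @param ct_noise_sd per-well Ct measurement noise SD (cycles).
#' @param host_ct_two_copy host ache Ct from two template copies at the
#'   reference DNA concentration.
#' @param host_ct_sd between-embryo SD of the host Ct (cycles).
#' @param conc_ct_slope cycles per log2 of DNA concentration (−1 = ideal).
#' @param allele_offsets per-genotype mean/SD of delta Ct(N−S), cycles.
#' @param dropout_cutoff Ct above which a reaction reads as non-detect.
#' @param dimer_rate probability a well contains only primer dimer.
#' @param dual_peak_rate probability a genuine well also shows a dimer peak.
#' @param amplicon_tm specific-amplicon melting temperature (degC).
#' @param dimer_tm_offset range (degC) the dimer peak falls below the
#'   amplicon peak.
#' @param n_replicates technical replicates per reaction (duplicates).
#' @param conc_median,conc_sdlog DNA-concentration lognormal parameters
#'   (ng/ul) for passing samples.
#' @param qc_fail_frac fraction of samples drawn to fail DNA QC.
#' @param metastasis_rate named per-phenotype metastasis probabilities
#'   (`sibling`, `mutant`); defaults are the study's observed 37.8% / 6.6%.
#' @param dispersed_pois_extra Poisson mean of dispersed cells beyond the
#'   5-cell minimum in metastatic embryos.
#' @param pixels_per_pg tumor blob area (pixels) per pg of human DNA.
#' @param image_size image dimensions `(rows, cols)`.
#' @param roi_center,roi_radii yolk ROI ellipse, pixels (`(x, y)` center).
#' @param spot_radius dispersed-cell disk radius, pixels.
#' @param cell_lines cell-line labels assigned to embryos.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_embryos = 60,
                       genotype_probs = c(WT_HOM = 0.25, HET = 0.5,
                                          MUT_HOM = 0.25),
                       load_median_pg = 400,
                       load_sigma_log = 0.5,
                       load_fold_mutant = 2.5,
                       engraft_rate = 0.8,
                       residual_frac = 0.02,
                       curve_slope = -3.3219,
                       curve_intercept = 30,
                       ct_noise_sd = 0.2,
                       host_ct_two_copy = 20,
                       host_ct_sd = 0.3,
                       conc_ct_slope = -1,
                       allele_offsets = list(
                         WT_HOM = c(mean = 9.85, sd = 1.07),
                         HET = c(mean = 0, sd = 0.3),
                         MUT_HOM = c(mean = -5.65, sd = 0.64)),
                       dropout_cutoff = 35,
                       dimer_rate = 0.02,
                       dual_peak_rate = 0.15,
                       amplicon_tm = 84,
                       dimer_tm_offset = c(8, 12),
                       n_replicates = 2,
                       conc_median = 60,
                       conc_sdlog = 0.35,
                       qc_fail_frac = 0.05,
                       metastasis_rate = c(sibling = 0.378, mutant = 0.066),
                       dispersed_pois_extra = 2,
                       pixels_per_pg = 1.5,
                       image_size = c(120, 200),
                       roi_center = c(55, 60),
                       roi_radii = c(32, 26),
                       spot_radius = 2,
                       cell_lines = c("Hep3B", "SKHep1")) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(genotype_probs) == 3, all(genotype_probs >= 0),
            abs(sum(genotype_probs) - 1) < 1e-8,
            load_median_pg > 0, load_sigma_log >= 0, load_fold_mutant > 0,
            engraft_rate >= 0, engraft_rate <= 1,
            ct_noise_sd >= 0, host_ct_sd >= 0,
            dropout_cutoff > 0, dimer_rate >= 0, dimer_rate <= 1,
            n_replicates >= 1, qc_fail_frac >= 0, qc_fail_frac < 1,
            all(unlist(metastasis_rate) >= 0),
            all(unlist(metastasis_rate) <= 1),
            pixels_per_pg > 0, length(image_size) == 2)
  names(genotype_probs) <- c("WT_HOM", "HET", "MUT_HOM")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# deterministic sub-stream seeds, kept within 32-bit integer range
.substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Simulate a xenografted cohort with ground truth
#'
#' Draws genotypes from the in-cross probabilities, lognormal human tumor
#' DNA loads (mutant median multiplied by `load_fold_mutant`), engraftment,
#' metastasis status and dispersed-cell counts, plus DNA-sample QC
#' measurements in which a configurable fraction of samples fails the
#' purity/concentration thresholds.
#'
#' @param cfg a [sim_config()].
#' @return list with `truth` (embryo_id, true_genotype, true_human_dna_pg,
#'   true_tumor_area, true_dispersed_count, engrafted), `samples` (DNA QC
#'   table), and `phenotype` (metadata skeleton: embryo_id, phenotype from
#'   the tail test, cell_line, experiment_set).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream(cfg$seed, 1L))
  n <- cfg$n_embryos
  id <- sprintf("E%04d", seq_len(n))
  genotype <- sample(names(cfg$genotype_probs), n, replace = TRUE,
                     prob = cfg$genotype_probs)
  meanlog <- log(cfg$load_median_pg) +
    log(cfg$load_fold_mutant) * (genotype == "MUT_HOM")
  pg <- rlnorm(n, meanlog, cfg$load_sigma_log)
  engrafted <- runif(n) < cfg$engraft_rate
  pg[!engrafted] <- pg[!engrafted] * cfg$residual_frac

  # image-scale truth: blob area tracks load, capped by the yolk ROI
  max_area <- floor(pi * (min(cfg$roi_radii) - 3)^2)
  area <- ifelse(engrafted,
                 pmin(round(cfg$pixels_per_pg * pg), max_area), 0L)

  phenotype <- ifelse(genotype == "MUT_HOM", "mutant", "wild_type_sibling")
  met_rate <- ifelse(phenotype == "mutant", cfg$metastasis_rate[["mutant"]],
                     cfg$metastasis_rate[["sibling"]])
  met <- engrafted & runif(n) < met_rate
  dispersed <- ifelse(met, 5L + rpois(n, cfg$dispersed_pois_extra),
                      ifelse(engrafted, pmin(rpois(n, 1), 4L), 0L))

  # DNA QC measurements: draw passing values, then push a chosen fraction
  # below one of the two hard thresholds
  conc <- pmax(rlnorm(n, log(cfg$conc_median), cfg$conc_sdlog), 31)
  a260_230 <- pmax(rnorm(n, 1.8, 0.25), 0.65)
  a260_280 <- rnorm(n, 1.9, 0.08)
  fail <- runif(n) < cfg$qc_fail_frac
  fail_kind <- runif(n) < 0.5
  conc[fail & fail_kind] <- runif(sum(fail & fail_kind), 5, 29.5)
  a260_230[fail & !fail_kind] <- runif(sum(fail & !fail_kind), 0.2, 0.59)

  truth <- data.frame(embryo_id = id, true_genotype = genotype,
                      true_human_dna_pg = pg, true_tumor_area = area,
                      true_dispersed_count = as.integer(dispersed),
                      engrafted = engrafted, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = id, concentration_ng_ul = conc,
                        a260_280 = a260_280, a260_230 = a260_230,
                        cell_line = sample(cfg$cell_lines, n, replace = TRUE),
                        experiment_set = sample(1:2, n, replace = TRUE),
                        stringsAsFactors = FALSE)
  phen <- data.frame(embryo_id = id, phenotype = phenotype,
                     cell_line = samples$cell_line,
                     experiment_set = samples$experiment_set,
                     stringsAsFactors = FALSE)
  list(truth = truth, samples = samples, phenotype = phen)
}

#' Simulate qPCR wells for a cohort
#'
#' Emits duplicate `ACHE_N`, `ACHE_S` and `ALU_YB8` wells per embryo. The
#' AluYb8 Ct follows the calibration line in `log10(true pg)`; the host
#' allele Ct values are built so that delta Ct(N−S) has the configured
#' per-genotype mean and SD, with the heterozygote alleles one cycle above
#' the two-copy homozygote anchor. Expected Ct values above the dropout
#' cutoff are emitted as raw over-cutoff values (mapped to non-detect by the
#' QC layer); dimer-only wells are injected at `dimer_rate` with melting
#' peaks 8–12 degC below the amplicon peak.
#'
#' @param truth the `truth` table from [simulate_cohort()].
#' @param cfg a [sim_config()].
#' @param samples optional `samples` table; when given, host Ct tracks
#'   `log2(concentration)` with slope `conc_ct_slope`.
#' @return a wells data frame in the same shape as [read_well_table()].
#' @export
simulate_qpcr <- function(truth, cfg, samples = NULL) {
  stopifnot(inherits(cfg, "sim_config"), nrow(truth) >= 1)
  set.seed(.substream(cfg$seed, 2L))
  n <- nrow(truth)
  g <- truth$true_genotype

  conc_term <- if (!is.null(samples)) {
    conc <- samples$concentration_ng_ul[match(truth$embryo_id,
                                              samples$sample_id)]
    cfg$conc_ct_slope * log2(conc / cfg$conc_median)
  } else 0
  u <- cfg$host_ct_two_copy + conc_term + rnorm(n, 0, cfg$host_ct_sd)

  off <- do.call(rbind, cfg$allele_offsets)
  delta <- rnorm(n, off[g, "mean"], off[g, "sd"])
  # two-copy anchor for homozygotes; each het allele is one doubling later
  ct_s0 <- ifelse(g == "WT_HOM", u,
                  ifelse(g == "MUT_HOM", u - delta, u + 1))
  ct_n0 <- ifelse(g == "WT_HOM", u + delta,
                  ifelse(g == "MUT_HOM", u, u + 1 + delta))
  ct_alu0 <- cfg$curve_intercept +
    cfg$curve_slope * log10(truth$true_human_dna_pg)

  reps <- cfg$n_replicates
  base <- rep(c(ct_n0, ct_s0, ct_alu0), times = reps)
  wells <- data.frame(
    sample_id = rep(rep(truth$embryo_id, 3), times = reps),
    primer_id = rep(rep(c("ACHE_N", "ACHE_S", "ALU_YB8"), each = n),
                    times = reps),
    ct_true = base,
    replicate = rep(seq_len(reps), each = 3 * n),
    stringsAsFactors = FALSE)
  m <- nrow(wells)
  ct_raw <- wells$ct_true + rnorm(m, 0, cfg$ct_noise_sd)

  tm_amp <- cfg$amplicon_tm + rnorm(m, 0, 0.3)
  tm_dim <- cfg$amplicon_tm - runif(m, cfg$dimer_tm_offset[1],
                                    cfg$dimer_tm_offset[2])
  dual <- runif(m) < cfg$dual_peak_rate
  tm_peaks <- lapply(seq_len(m), function(i) {
    if (dual[i]) c(tm_amp[i], tm_dim[i]) else tm_amp[i]
  })

  dimer <- runif(m) < cfg$dimer_rate
  if (any(dimer)) {
    ct_raw[dimer] <- runif(sum(dimer), 30, 34)
    tm_peaks[dimer] <- lapply(tm_dim[dimer], identity)
  }

  nd <- apply_nondetect(pmax(ct_raw, 0), cfg$dropout_cutoff)
  out <- data.frame(row = seq_len(m), sample_id = wells$sample_id,
                    primer_id = wells$primer_id,
                    ct = nd$ct, ct_raw = pmax(ct_raw, 0),
                    nondetect = nd$nondetect,
                    replicate = wells$replicate, stringsAsFactors = FALSE)
  out$tm_peaks <- tm_peaks
  out
}

#' Simulate a standard dilution series
#'
#' Seven ten-fold steps of human DNA from 10 ng (1e4 pg) down to 0.01 pg in
#' a constant zebrafish DNA background. Points whose expected Ct exceeds the
#' dropout cutoff are emitted as non-detects, so the empirical LOD of the
#' fitted curve is a design point of the configuration (0.1 pg under the
#' defaults).
#'
#' @param cfg a [sim_config()].
#' @return data frame with `human_dna_pg` and `ct` (`NA` = non-detect).
#' @export
simulate_standards <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream(cfg$seed, 3L))
  pg <- 10^(4:-2)
  expected <- cfg$curve_intercept + cfg$curve_slope * log10(pg)
  ct <- expected + rnorm(length(pg), 0, cfg$ct_noise_sd)
  ct[expected > cfg$dropout_cutoff] <- NA_real_
  data.frame(human_dna_pg = pg, ct = ct)
}

# place k non-overlapping spot centers on a jittered grid in the tail
.spot_centers <- function(k, cfg) {
  x0 <- ceiling(cfg$roi_center[1] + cfg$roi_radii[1] + 3 * cfg$spot_radius)
  step <- 4 * cfg$spot_radius - 1
  xs <- seq(x0, cfg$image_size[2] - cfg$spot_radius - 1, by = step)
  ys <- seq(cfg$spot_radius + 2, cfg$image_size[1] - cfg$spot_radius - 1,
            by = step)
  grid <- expand.grid(x = xs, y = ys)
  if (k > nrow(grid)) stop("image too small for dispersed-cell count",
                           call. = FALSE)
  idx <- sample(nrow(grid), k)
  grid[idx, , drop = FALSE]
}

#' Simulate a larva fluorescence image
#'
#' One grayscale image per embryo: Gaussian background, a bright tumor disk
#' of the ground-truth area centered in the yolk ROI, and the ground-truth
#' number of dispersed-cell spots placed on a jittered grid in the tail
#' region (strictly outside the ROI). Deterministic given the configuration
#' seed and the embryo's index.
#'
#' @param truth the `truth` table from [simulate_cohort()].
#' @param cfg a [sim_config()].
#' @param which row index of the embryo to image.
#' @return list with `image` (matrix) and `roi` (a [yolk_roi()]).
#' @export
simulate_larva_image <- function(truth, cfg, which = 1) {
  stopifnot(inherits(cfg, "sim_config"), which >= 1, which <= nrow(truth))
  set.seed(.substream(cfg$seed, 100L + as.integer(which)))
  nr <- cfg$image_size[1]; nc <- cfg$image_size[2]
  img <- matrix(pmax(rnorm(nr * nc, 10, 3), 0), nr, nc)
  roi <- yolk_roi(cfg$roi_center, cfg$roi_radii)

  area <- truth$true_tumor_area[which]
  if (area > 0) {
    r <- sqrt(area / pi)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    blob <- (cols - roi$center[1])^2 + (rows - roi$center[2])^2 <= r^2
    img[blob] <- 160 + rnorm(sum(blob), 0, 8)
  }
  k <- truth$true_dispersed_count[which]
  if (k > 0) {
    centers <- .spot_centers(k, cfg)
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (i in seq_len(k)) {
      spot <- (cols - centers$x[i])^2 + (rows - centers$y[i])^2 <=
        cfg$spot_radius^2
      img[spot] <- 150 + rnorm(sum(spot), 0, 8)
    }
  }
  list(image = img, roi = roi)
}
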