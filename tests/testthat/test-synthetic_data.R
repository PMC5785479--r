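test_that("sim_config validates its stated world", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, genotype_probs = c(0.5, 0.4, 0.3)))
  cfg <- sim_config(seed = 1)
  expect_equal(unname(cfg$genotype_probs), c(0.25, 0.5, 0.25))
  expect_equal(cfg$load_fold_mutant, 2.5)
  expect_equal(cfg$curve_slope, -3.3219)
  expect_equal(cfg$allele_offsets$WT_HOM[["mean"]], 9.85)
  expect_equal(cfg$allele_offsets$MUT_HOM[["mean"]], -5.65)
  expect_equal(cfg$dropout_cutoff, 35)
})

test_that("genotype draws follow the Mendelian in-cross ratio", {
  cfg <- sim_config(seed = 8, n_embryos = 4000)
  sim <- simulate_cohort(cfg)
  frac <- table(sim$truth$true_genotype) / 4000
  expect_lt(abs(frac[["WT_HOM"]] - 0.25), 0.02)
  expect_lt(abs(frac[["HET"]] - 0.50), 0.02)
  expect_lt(abs(frac[["MUT_HOM"]] - 0.25), 0.02)
})

test_that("the mutant load fold acts on the median and vanishes at fold 1", {
  cfg <- sim_config(seed = 9, n_embryos = 6000, engraft_rate = 1)
  sim <- simulate_cohort(cfg)
  med <- tapply(sim$truth$true_human_dna_pg, sim$truth$true_genotype, median)
  expect_equal(unname(med[["MUT_HOM"]] / med[["WT_HOM"]]), 2.5,
               tolerance = 0.1)

  null_cfg <- sim_config(seed = 9, n_embryos = 6000, engraft_rate = 1,
                         load_fold_mutant = 1)
  sim0 <- simulate_cohort(null_cfg)
  mean_log <- tapply(log(sim0$truth$true_human_dna_pg),
                     sim0$truth$true_genotype, mean)
  expect_lt(abs(mean_log[["MUT_HOM"]] - mean_log[["WT_HOM"]]), 0.05)
})

test_that("QC failures are injected at the configured fraction", {
  cfg <- sim_config(seed = 10, n_embryos = 4000, qc_fail_frac = 0.1)
  sim <- simulate_cohort(cfg)
  verdict <- qc_filter_sample(sim$samples)
  expect_lt(abs(mean(!verdict$pass) - 0.1), 0.02)
  # passing draws always clear both thresholds by construction
  ok <- sim$samples[verdict$pass, ]
  expect_true(all(ok$concentration_ng_ul >= 30 & ok$a260_230 > 0.6))
})

test_that("halving true human DNA raises the AluYb8 Ct by one cycle", {
  cfg <- noise_free_config(seed = 11, n_embryos = 10)
  sim <- simulate_cohort(cfg)
  wells <- simulate_qpcr(sim$truth, cfg, sim$samples)
  half <- sim$truth
  half$true_human_dna_pg <- half$true_human_dna_pg / 2
  wells2 <- simulate_qpcr(half, cfg, sim$samples)
  alu1 <- wells$ct[wells$primer_id == "ALU_YB8"]
  alu2 <- wells2$ct[wells2$primer_id == "ALU_YB8"]
  expect_equal(mean(alu2 - alu1), -cfg$curve_slope * log10(2),
               tolerance = 1e-10)
})

test_that("default-noise cohorts are recovered at >= 99%", {
  cfg <- sim_config(seed = 12, n_embryos = 1000)
  sim <- simulate_cohort(cfg)
  wells <- simulate_qpcr(sim$truth, cfg, sim$samples)
  res <- run_load_pipeline(wells, qc_config(amplicon_tm = cfg$amplicon_tm))
  calls <- res$genotypes$calls
  truth <- sim$truth$true_genotype[match(calls$sample_id,
                                         sim$truth$embryo_id)]
  expect_gte(mean(as.character(calls$call) == truth), 0.99)
})

test_that("standard series has the designed LOD and noise-free linearity", {
  cfg <- sim_config(seed = 13)
  std <- simulate_standards(cfg)
  expect_equal(std$human_dna_pg, 10^(4:-2))
  expect_true(is.na(std$ct[std$human_dna_pg == 0.01]))
  fit <- fit_standard_curve(std, cutoff = cfg$dropout_cutoff)
  expect_equal(fit$lod_pg, 0.1)

  nf <- noise_free_config(seed = 13)
  fit0 <- fit_standard_curve(simulate_standards(nf))
  expect_equal(fit0$slope, nf$curve_slope, tolerance = 1e-9)
  expect_equal(fit0$intercept, nf$curve_intercept, tolerance = 1e-9)

  # all points below the cutoff: insufficient curve
  dark <- sim_config(seed = 13, curve_intercept = 80)
  expect_error(fit_standard_curve(simulate_standards(dark)),
               "insufficient curve")
})

test_that("dimer wells carry only out-of-window melting peaks", {
  cfg <- sim_config(seed = 14, n_embryos = 300, dimer_rate = 0.3)
  sim <- simulate_cohort(cfg)
  wells <- simulate_qpcr(sim$truth, cfg, sim$samples)
  out <- suppressWarnings(
    qc_filter_well(wells, qc_config(amplicon_tm = cfg$amplicon_tm)))
  frac_dimer <- mean(out$verdict == "dimer_only")
  expect_lt(abs(frac_dimer - 0.3), 0.05)
  dimer_peaks <- unlist(out$tm_peaks[out$verdict == "dimer_only"])
  expect_true(all(dimer_peaks <= cfg$amplicon_tm - cfg$dimer_tm_offset[1]))
})

test_that("larva images reproduce their ground truth", {
  cfg <- sim_config(seed = 15, n_embryos = 30)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth

  # an embryo without engraftment yields a signal-free image
  idx0 <- which(!truth$engrafted)[1]
  expect_false(is.na(idx0))  # present under this seed by construction
  li0 <- simulate_larva_image(truth, cfg, idx0)
  expect_equal(segment_tumor_area(li0$image, li0$roi)$tumor_area, 0L)

  # a metastatic embryo: spot count and classification match the truth
  idx6 <- which(truth$true_dispersed_count >= 6)[1]
  expect_false(is.na(idx6))  # present under this seed by construction
  li6 <- simulate_larva_image(truth, cfg, idx6)
  n_cells <- count_dispersed_cells(li6$image, li6$roi)
  expect_equal(n_cells, truth$true_dispersed_count[idx6])
  cls <- classify_embryo(segment_tumor_area(li6$image, li6$roi)$tumor_area,
                         n_cells)
  expect_equal(as.character(cls$status), "invaded")
  expect_true(cls$metastasis_positive)
})

test_that("doubling the true load doubles the blob target area", {
  cfg <- noise_free_config(seed = 16, n_embryos = 8, load_median_pg = 200,
                           load_fold_mutant = 1)
  cfg2 <- noise_free_config(seed = 16, n_embryos = 8, load_median_pg = 400,
                            load_fold_mutant = 1)
  a1 <- simulate_cohort(cfg)$truth$true_tumor_area
  a2 <- simulate_cohort(cfg2)$truth$true_tumor_area
  expect_equal(a2 / a1, rep(2, 8), tolerance = 0.01)
})

test_that("observable tables are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 17, n_embryos = 40)
  s1 <- simulate_cohort(cfg); s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  w1 <- simulate_qpcr(s1$truth, cfg, s1$samples)
  w2 <- simulate_qpcr(s2$truth, cfg, s2$samples)
  expect_identical(w1, w2)
  expect_identical(simulate_standards(cfg), simulate_standards(cfg))
  i1 <- simulate_larva_image(s1$truth, cfg, 3)
  i2 <- simulate_larva_image(s2$truth, cfg, 3)
  expect_identical(i1, i2)

  # different seeds give different draws
  s3 <- simulate_cohort(sim_config(seed = 18, n_embryos = 40))
  expect_false(identical(s1$truth$true_human_dna_pg,
                         s3$truth$true_human_dna_pg))

  # ground truth and observables share embryo ids one-to-one
  expect_setequal(s1$truth$embryo_id, s1$samples$sample_id)
  expect_setequal(s1$truth$embryo_id, unique(w1$sample_id))
})
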