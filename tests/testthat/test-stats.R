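test_that("t_test handles identical, degenerate and directional inputs", {
  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)

  one <- t_test(c(1, 2, 3), c(1, 2, 3), tails = "one", direction = "greater")
  expect_equal(one$p_value, 0.5)

  deg <- t_test(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  # one-tailed p and its mirrored-direction complement sum to 1
  set.seed(71)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  pg <- t_test(a, b, tails = "one", direction = "greater")$p_value
  pl <- t_test(a, b, tails = "one", direction = "less")$p_value
  expect_equal(pg + pl, 1, tolerance = 1e-12)
  expect_true(pg >= 0 && pg <= 1)

  # pooled variance matches the classic Student statistic
  pooled <- t_test(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref$statistic))
  expect_equal(pooled$df, unname(ref$parameter))
})

test_that("t_test holds its type-I error rate under the null", {
  set.seed(72)
  n_rep <- 1e4
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(8); b <- rnorm(8)  # true shift 0
    rej[i] <- t_test(a, b)$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("anova_tukey finds the shifted group and only it", {
  set.seed(73)
  # three identical groups: F ~ 0, adjusted p ~ 1
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  null_fit <- anova_tukey(v, g)
  expect_lt(null_fit$omnibus$statistic, 1e-10)
  expect_true(all(null_fit$contrasts$p_adj > 0.999))

  # one strongly shifted group: its two contrasts significant, third not
  values <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 5, 0.1))
  group <- rep(c("a", "b", "c"), each = 10)
  fit <- anova_tukey(values, group)
  expect_lt(fit$omnibus$p_value, 1e-6)
  p <- setNames(fit$contrasts$p_adj, fit$contrasts$contrast)
  expect_lt(p[["c-a"]], 0.001)
  expect_lt(p[["c-b"]], 0.001)
  expect_gt(p[["b-a"]], 0.05)

  # permutation oracle for the omnibus test
  f_obs <- fit$omnibus$statistic
  f_perm <- replicate(500, {
    anova_tukey(values, sample(group))$omnibus$statistic
  })
  expect_lt(mean(f_perm >= f_obs), 0.01)
})

test_that("two-level ANOVA equals the two-sided pooled t-test", {
  set.seed(74)
  a <- rnorm(8); b <- rnorm(9, 0.4)
  fit <- anova_tukey(c(a, b), rep(c("a", "b"), c(8, 9)))
  tt <- t_test(a, b)
  expect_equal(fit$omnibus$p_value, tt$p_value, tolerance = 1e-12)
  expect_equal(fit$omnibus$statistic, tt$statistic^2, tolerance = 1e-10)
})

test_that("anova_tukey excludes undersized levels with a warning", {
  v <- c(rnorm(5), rnorm(5, 1), 7)
  g <- c(rep("a", 5), rep("b", 5), "c")
  expect_warning(fit <- anova_tukey(v, g), "n < 2")
  expect_equal(nrow(fit$contrasts), 1)
})

test_that("factorial_anova isolates a pure genotype effect", {
  set.seed(75)
  des <- expand.grid(genotype = c("wt", "mut"),
                     cell_line = c("Hep3B", "SKHep1"),
                     set = c("1", "2"))
  des <- des[rep(seq_len(nrow(des)), each = 8), ]
  y <- rnorm(nrow(des), 0, 0.5) + 3 * (des$genotype == "mut")
  fit <- factorial_anova(y, des)
  p <- setNames(fit$table$p_value, fit$table$term)
  expect_lt(p[["genotype"]], 1e-10)
  expect_true(all(p[setdiff(names(p), c("genotype", "Residuals"))] > 0.01,
                  na.rm = TRUE))
  expect_equal(fit$ss_type, "II")
})

test_that("Type II equals Type I on balanced designs", {
  set.seed(76)
  des <- expand.grid(g = c("a", "b", "c"), c = c("x", "y"))
  des <- des[rep(seq_len(nrow(des)), each = 5), ]
  y <- rnorm(nrow(des)) + (des$g == "a") * 1.2 + (des$c == "x") * 0.7
  fit <- factorial_anova(y, des)
  ref <- anova(lm(y ~ g * c, data = cbind(des, y = y)))
  for (term in c("g", "c", "g:c")) {
    expect_equal(fit$table$sum_sq[fit$table$term == term],
                 ref[term, "Sum Sq"], tolerance = 1e-10, info = term)
  }
})

test_that("factorial_anova rejects bad designs with informative errors", {
  expect_error(factorial_anova(rnorm(6), data.frame(g = rep(c("a", "b"), 3))),
               "anova_tukey")
  des <- data.frame(g = c("a", "a", "b", "b"), c = c("x", "x", "x", "x"))
  des$c <- factor(des$c, levels = c("x", "y"))
  expect_error(factorial_anova(rnorm(4), des), "empty design cell")
})

test_that("factorial_anova keeps each term near the nominal level on noise", {
  set.seed(77)
  des <- expand.grid(g = c("a", "b"), c = c("x", "y"))
  des <- des[rep(seq_len(nrow(des)), each = 6), ]
  n_rep <- 1000
  rej <- matrix(FALSE, n_rep, 3)
  for (i in seq_len(n_rep)) {
    fit <- factorial_anova(rnorm(nrow(des)), des)
    rej[i, ] <- fit$table$p_value[1:3] < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(abs(rates - 0.05) < 0.02))
})

test_that("chi_square_2x2 matches the closed form and its invariances", {
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # hand-computed sum((O-E)^2/E) oracle
  obs <- c(20, 80, 5, 95)
  m <- matrix(obs, 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat_oracle <- sum((m - e)^2 / e)
  fit <- chi_square_2x2(20, 80, 5, 95)
  expect_equal(fit$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(fit$df, 1)

  # invariant under simultaneous row and column swap
  swapped <- chi_square_2x2(95, 5, 80, 20)
  expect_equal(swapped$statistic, fit$statistic, tolerance = 1e-12)

  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(chi_square_2x2(0, 0, 5, 5), "degenerate")
  # Yates correction is available but off by default
  expect_lt(chi_square_2x2(20, 80, 5, 95, correct = TRUE)$statistic,
            fit$statistic)
})

test_that("pearson recovers exact linear relationships", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson(1:2, 2:3), "at least 3")
  const <- pearson(rep(1, 5), rnorm(5))
  expect_true(is.na(const$r))
  expect_match(const$note, "undefined")
})

test_that("pearson p-values are uniform under independence", {
  set.seed(78)
  n_rep <- 1e4
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    p[i] <- pearson(rnorm(20), rnorm(20))$p_value
  }
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
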