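## Group-comparison statistics used by the xenograft study, wrapped behind
## explicit contracts: Student's t (one- or two-tailed), one-way ANOVA with
## Tukey HSD, 2/3-factor factorial ANOVA with Type II sums of squares,
## Pearson chi-square on 2x2 tables, and Pearson correlation.

#' Container for a single test result
#'
#' @param statistic test statistic.
#' @param p_value p-value in `[0, 1]`.
#' @param df degrees of freedom (scalar or pair).
#' @param tails `"two"` or `"one"`.
#' @param direction for one-tailed tests, the tested direction of group A
#'   relative to group B.
#' @param adjusted whether the p-value is multiplicity-adjusted.
#' @param contrast label of the compared groups or term.
#' @param method human-readable method name.
#' @param degenerate flag for degenerate inputs (e.g. zero pooled variance).
#' @return an object of class `test_result`.
#' @export
test_result <- function(statistic, p_value, df = NA_real_, tails = "two",
                        direction = NA_character_, adjusted = FALSE,
                        contrast = NA_character_, method = "",
                        degenerate = FALSE) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 tails = tails, direction = direction, adjusted = adjusted,
                 contrast = contrast, method = method,
                 degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s-tailed%s)%s\n",
              x$method, x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value, x$tails,
              if (!is.na(x$direction)) paste0(", ", x$direction) else "",
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

#' Student's two-sample t-test
#'
#' Pooled-variance Student's t by default (`var_equal = FALSE` gives Welch).
#' For a one-tailed test, `direction` states the alternative for group A
#' versus group B; the one-tailed p is half the two-tailed p when the
#' observed difference matches the stated direction and one minus that half
#' otherwise. Groups that are jointly constant (zero pooled variance) with
#' equal means return p = 1 with a degenerate flag.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @param tails `"two"` (default) or `"one"`.
#' @param direction one-tailed alternative: `"greater"` (mean(a) > mean(b))
#'   or `"less"`.
#' @param var_equal pool the variances (classic Student) when `TRUE`.
#' @return a [test_result()].
#' @examples
#' t_test(c(1, 2, 3), c(1, 2, 3), tails = "one", direction = "greater")
#' @export
t_test <- function(a, b, tails = c("two", "one"),
                   direction = c("greater", "less"), var_equal = TRUE) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- mean(a) == mean(b)
    return(test_result(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                       p_value = if (equal) 1 else 0,
                       df = length(a) + length(b) - 2, tails = tails,
                       direction = if (tails == "one") direction else NA_character_,
                       method = "Student's t-test", degenerate = TRUE))
  }
  alt <- if (tails == "two") "two.sided" else direction
  fit <- t.test(a, b, alternative = alt, var.equal = var_equal)
  test_result(statistic = unname(fit$statistic), p_value = fit$p.value,
              df = unname(fit$parameter), tails = tails,
              direction = if (tails == "one") direction else NA_character_,
              method = if (var_equal) "Student's t-test" else "Welch t-test")
}

#' One-way ANOVA followed by Tukey's HSD
#'
#' Omnibus F-test across the factor levels, then all pairwise contrasts with
#' Tukey honest-significant-difference adjustment (family-wise error
#' preserved). Levels with fewer than two observations are excluded with a
#' warning.
#'
#' @param values numeric response.
#' @param group factor (or coercible) of group labels, same length.
#' @return list of class `anova_tukey` with `omnibus` (a [test_result()])
#'   and `contrasts` (data frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, group) {
  stopifnot(length(values) == length(group), all(is.finite(values)))
  group <- factor(group)
  counts <- table(group)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning(sprintf("excluding level(s) with n < 2: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !group %in% small
    values <- values[keep]
    group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2) stop("need >= 2 levels with n >= 2", call. = FALSE)
  dat <- data.frame(values = values, group = group)
  fit <- aov(values ~ group, data = dat)
  tab <- summary(fit)[[1]]
  omnibus <- test_result(statistic = tab[1, "F value"],
                         p_value = tab[1, "Pr(>F)"],
                         df = c(tab[1, "Df"], tab[2, "Df"]),
                         method = "One-way ANOVA")
  hsd <- TukeyHSD(fit)$group
  contrasts <- data.frame(contrast = rownames(hsd),
                          diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                          upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(omnibus = omnibus, contrasts = contrasts),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  print(x$omnibus)
  cat("Tukey HSD contrasts:\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

# does term label a (e.g. "g:c") contain term label b ("g")?
.term_contains <- function(a, b) {
  fa <- strsplit(a, ":", fixed = TRUE)[[1]]
  fb <- strsplit(b, ":", fixed = TRUE)[[1]]
  all(fb %in% fa) && length(fa) > length(fb)
}

#' Factorial ANOVA with Type II sums of squares
#'
#' Full-factorial model (all interactions) over two or three crossed factors
#' such as genotype, cell line and experiment set. Each term's Type II sum
#' of squares is the reduction in residual SS when the term is added to the
#' model containing every other term that does not contain it (order
#' invariant for main effects; identical to Type I on balanced designs).
#' F-statistics use the full model's residual mean square.
#'
#' @param values numeric response.
#' @param factors data frame of 2 or 3 factor columns (an error directs
#'   single-factor designs to [anova_tukey()]); every cell of the full
#'   design must be non-empty.
#' @return list of class `factorial_anova` with `table` (data frame: `term`,
#'   `df`, `sum_sq`, `statistic`, `p_value`, plus a Residuals row) and
#'   `ss_type = "II"`.
#' @export
factorial_anova <- function(values, factors) {
  stopifnot(is.data.frame(factors), length(values) == nrow(factors),
            all(is.finite(values)))
  if (ncol(factors) < 2) {
    stop("single-factor input: use anova_tukey()", call. = FALSE)
  }
  if (ncol(factors) > 3) stop("at most 3 factors supported", call. = FALSE)
  # keep declared (possibly empty) levels so empty cells are caught
  factors[] <- lapply(factors, function(f) if (is.factor(f)) f else factor(f))
  cells <- table(factors)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    lab <- paste(mapply(function(d, i) dimnames(cells)[[d]][i],
                        seq_along(empty), empty),
                 collapse = " x ")
    stop(sprintf("empty design cell: %s", lab), call. = FALSE)
  }
  dat <- cbind(.y = values, factors)
  form <- stats::as.formula(paste(".y ~", paste(names(factors),
                                                collapse = " * ")))
  full <- lm(form, data = dat)
  X <- model.matrix(full)
  assign <- attr(X, "assign")
  labels <- attr(terms(full), "term.labels")
  rss <- function(cols) {
    fit <- lm.fit(X[, cols, drop = FALSE], values)
    sum(fit$residuals^2)
  }
  rss_full <- sum(full$residuals^2)
  df_res <- full$df.residual
  mse <- rss_full / df_res

  rows <- lapply(seq_along(labels), function(j) {
    term <- labels[j]
    others <- which(!vapply(labels, .term_contains, TRUE, b = term) &
                      labels != term)
    base_cols <- which(assign %in% c(0L, others))
    with_cols <- which(assign %in% c(0L, others, j))
    ss <- rss(base_cols) - rss(with_cols)
    df <- sum(assign == j)
    f <- (ss / df) / mse
    data.frame(term = term, df = df, sum_sq = ss, statistic = f,
               p_value = pf(f, df, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(term = "Residuals", df = df_res,
                               sum_sq = rss_full, statistic = NA_real_,
                               p_value = NA_real_, stringsAsFactors = FALSE))
  structure(list(table = tab, ss_type = "II"), class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat(sprintf("Factorial ANOVA (Type %s sums of squares)\n", x$ss_type))
  print(x$table, digits = 4)
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Continuity correction is off by default (set `correct = TRUE` for Yates).
#' Table layout: rows are groups, columns outcomes — `a`, `b` are the first
#' row, `c`, `d` the second. A zero row or column marginal is degenerate.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param correct apply Yates continuity correction.
#' @return a [test_result()] with df = 1.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("degenerate table", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table", call. = FALSE)
  }
  fit <- suppressWarnings(chisq.test(m, correct = correct))
  test_result(statistic = unname(fit$statistic), p_value = fit$p.value,
              df = unname(fit$parameter),
              method = if (correct) "Chi-square (Yates)" else "Chi-square")
}

#' Pearson product-moment correlation
#'
#' Two-sided p from the t transform. Zero variance in either vector makes r
#' undefined; it is reported as such rather than erroring.
#'
#' @param x,y paired numeric vectors, n >= 3, finite.
#' @return list with `r`, `statistic` (t), `df`, `p_value`, `n`, and `note`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, statistic = NA_real_, df = n - 2,
                p_value = NA_real_, n = n,
                note = "r undefined (zero variance)"))
  }
  fit <- cor.test(x, y)
  list(r = unname(fit$estimate), statistic = unname(fit$statistic),
       df = unname(fit$parameter), p_value = fit$p.value, n = n, note = "")
}
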