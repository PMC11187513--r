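# One-way ANOVA effect size, noncentral-F power, balanced sample-size
# search, and a thin standardized multivariable regression reporter.

#' Cohen's f from group summaries
#'
#' \eqn{f = \sigma_m / s_{pooled}} with
#' \eqn{\sigma_m = \sqrt{\sum_g n_g (m_g - \bar{m})^2 / N}} (the
#' n-weighted between-group SD around the weighted grand mean) and
#' \eqn{s_{pooled}} the pooled within-group SD.
#'
#' @param n,mean,sd equal-length vectors of per-group size, mean and SD
#'   (>= 2 groups, n >= 2 and sd > 0 each).
#' @return Cohen's f (nonnegative).
#' @examples
#' cohensF(n = c(10, 10, 10), mean = c(-1, 0, 1), sd = c(1, 1, 1)) # sqrt(2/3)
#' @export
cohensF <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd))
  if (length(n) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  N <- sum(n)
  sp2 <- sum((n - 1) * sd^2) / (N - length(n))
  if (sp2 <= 0) stop("zero pooled within-group SD", call. = FALSE)
  gm <- sum(n * mean) / N
  sqrt(sum(n * (mean - gm)^2) / N) / sqrt(sp2)
}

#' Power of the one-way ANOVA omnibus F test
#'
#' Fixed-effects omnibus power via the noncentral F distribution:
#' \eqn{power = P(F'(k-1, N-k, \lambda) > F_{crit}(k-1, N-k, \alpha))}
#' with noncentrality \eqn{\lambda = f^2 N}.
#'
#' @param N total sample size across groups.
#' @param kGroups number of groups (>= 2).
#' @param f Cohen's f effect size.
#' @param alpha significance level.
#' @return power in (0, 1); equals `alpha` when `f = 0`.
#' @export
powerOnewayNcF <- function(N, kGroups, f, alpha = 0.05) {
  stopifnot(kGroups >= 2L, f >= 0, alpha > 0, alpha < 1)
  if (N < kGroups + 1L) stop("N must exceed the number of groups", call. = FALSE)
  df1 <- kGroups - 1L
  df2 <- N - kGroups
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = f^2 * N, lower.tail = FALSE)
}

#' Smallest balanced total sample size reaching a target power
#'
#' Searches total N upward in multiples of `kGroups` (equal allocation,
#' minimum 2 per group) until the omnibus noncentral-F power reaches
#' `targetPower`.
#'
#' @param kGroups number of groups.
#' @param f Cohen's f (> 0).
#' @param alpha significance level.
#' @param targetPower required power in (0, 1).
#' @param maxN search cap; exceeding it is an error (power unreachable
#'   at this f).
#' @return total N (a multiple of `kGroups`).
#' @examples
#' requiredBalancedN(kGroups = 3, f = 1.16, alpha = 0.05, targetPower = 0.90)
#' @export
requiredBalancedN <- function(kGroups, f, alpha = 0.05, targetPower = 0.90,
                              maxN = 100000L) {
  stopifnot(kGroups >= 2L, targetPower > 0, targetPower < 1)
  if (f <= 0) stop("f must be positive for a sample-size search", call. = FALSE)
  kGroups <- as.integer(kGroups)
  N <- 2L * kGroups
  while (powerOnewayNcF(N, kGroups, f, alpha) < targetPower) {
    N <- N + kGroups
    if (N > maxN)
      stop("target power unreachable below N = ", maxN, " at f = ", f,
           call. = FALSE)
  }
  N
}

#' Standardized multivariable regression report
#'
#' Ordinary least squares on the z-scored response and predictors:
#' per-predictor standardized coefficients with their SEs and p
#' values, plus the adjusted R-squared.  Complete cases only.
#'
#' @param table data.frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns.
#' @return list with `coefficients` (data.frame `term`, `beta`, `se`,
#'   `p`), `adj_r_squared` and `n` (complete cases used).
#' @export
standardizedRegression <- function(table, response, predictors) {
  stopifnot(is.data.frame(table), response %in% names(table),
            all(predictors %in% names(table)))
  dat <- table[, c(response, predictors), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L)
    stop("need at least ", length(predictors) + 2L, " complete cases",
         call. = FALSE)
  z <- as.data.frame(lapply(dat, function(col) {
    s <- sd(col)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(col)))
    (col - mean(col)) / s
  }))
  const <- names(z)[vapply(z, function(col) all(is.na(col)), TRUE)]
  if (length(const))
    stop("constant column(s): ", paste(const, collapse = ", "), call. = FALSE)
  fml <- stats::as.formula(paste(
    sprintf("`%s`", response), "~",
    paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(fml, data = z)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(gsub("`", "", bad), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients[-1L, , drop = FALSE]  # drop intercept (~0 by centering)
  list(
    coefficients = data.frame(
      term = gsub("`", "", rownames(ct)),
      beta = unname(ct[, 1L]), se = unname(ct[, 2L]), p = unname(ct[, 4L]),
      stringsAsFactors = FALSE),
    adj_r_squared = sm$adj.r.squared,
    n = nrow(dat))
}
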