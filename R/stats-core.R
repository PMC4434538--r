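#' @title Statistical primitives
#' @description Empirical-Bayes moderated t-tests (gene-wise simple linear
#'   models with variances shrunk toward a common prior fitted by the method
#'   of moments on log sample variances), exact tests for contingency tables,
#'   Wilson score intervals, and Welch t-tests.
#' @name stats-core
NULL

# Invert the trigamma function: find x > 0 with trigamma(x) = y.
inv_trigamma <- function(y) {
  if (y <= 0) return(Inf)
  if (y > trigamma(1e-8)) return(1e-8)
  stats::uniroot(function(x) trigamma(x) - y, lower = 1e-8, upper = 1e8,
                 tol = .Machine$double.eps^0.5)$root
}

#' Empirical-Bayes variance shrinkage
#'
#' Fits the standard hierarchical model for gene-wise residual variances
#' (scaled chi-square likelihood, scaled inverse chi-square prior with prior
#' df `d0` and prior variance `s0^2`) by the method of moments on
#' `log(s^2)`, then returns posterior variances
#' `(d0*s0^2 + df*s^2) / (d0 + df)`.
#'
#' @param s2 gene-wise residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param prior_df optional override of the fitted prior df; `0` gives back the
#'   raw variances (ordinary t), `Inf` forces every posterior variance to
#'   `s0^2`.
#' @return list with `df_prior`, `var_prior`, `var_post`.
#' @export
squeeze_var <- function(s2, df, prior_df = NULL) {
  stopifnot(length(df) == 1L, df > 0)
  z <- log(s2[is.finite(s2) & s2 > 0])
  if (length(z) < 2L) stop("need at least two positive finite variances")
  e_adj <- digamma(df / 2) - log(df / 2)  # E[log(chi2_df/df)]
  if (is.null(prior_df)) {
    excess <- stats::var(z) - trigamma(df / 2)
    d0 <- if (is.finite(excess) && excess > 0) 2 * inv_trigamma(excess) else Inf
  } else d0 <- prior_df
  s02 <- if (is.finite(d0) && d0 > 0)
    exp(mean(z) - e_adj + digamma(d0 / 2) - log(d0 / 2))
  else exp(mean(z) - e_adj)
  var_post <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + df * s2) / (d0 + df)
  list(df_prior = d0, var_prior = s02, var_post = var_post)
}

#' Gene-wise moderated t-tests
#'
#' For every gene, fits a simple linear model with intercept and computes a
#' t-statistic for the slope using an empirical-Bayes posterior residual
#' variance (see [squeeze_var()]); p-values are two-sided on `d0 + df` degrees
#' of freedom. With `genes_as = "outcome"` (default) each gene's expression is
#' regressed on `response` (the usual differential-expression direction, used
#' for covariate gene selection). With `genes_as = "predictor"` the shared
#' `response` vector (e.g. baseline-model residuals) is regressed on each
#' gene's expression, so residual variances are on a common scale across
#' genes.
#'
#' @param expression genes x samples matrix.
#' @param response per-sample numeric vector (binary factors are coded 0/1).
#' @param genes_as whether genes are the regression outcome or the predictor.
#' @param prior_df optional prior-df override passed to [squeeze_var()].
#' @return data.frame (one row per gene): `gene`, `effect` (slope), `s2`
#'   (residual variance), `df`, `s2_post`, `t`, `p`; prior df and prior
#'   variance attached as attributes `df_prior`, `var_prior`.
#' @export
moderated_t <- function(expression, response,
                        genes_as = c("outcome", "predictor"),
                        prior_df = NULL) {
  genes_as <- match.arg(genes_as)
  validate_expression(expression)
  if (is.factor(response)) response <- as.integer(response) - 1L
  if (is.logical(response)) response <- as.numeric(response)
  response <- as.numeric(response)
  n <- ncol(expression)
  if (length(response) != n) stop("response length must match sample count")
  if (n < 3L) stop("moderated_t needs at least 3 samples")
  if (stats::var(response) == 0) stop("response is constant across samples")
  df <- n - 2L

  yc <- response - mean(response)
  ec <- expression - rowMeans(expression)
  if (genes_as == "outcome") {
    sxx <- sum(yc^2)
    beta <- drop(ec %*% yc) / sxx
    syy <- rowSums(ec^2)
    rss <- pmax(syy - beta^2 * sxx, 0)
    v <- 1 / sxx                       # var(beta) = sigma^2 * v
  } else {
    sxx <- rowSums(ec^2)
    if (any(sxx == 0)) stop("constant gene(s): ",
                            paste(rownames(expression)[sxx == 0], collapse = ", "))
    beta <- drop(ec %*% yc) / sxx
    syy <- sum(yc^2)
    rss <- pmax(syy - beta^2 * sxx, 0)
    v <- 1 / sxx
  }
  s2 <- rss / df
  sq <- squeeze_var(s2, df, prior_df = prior_df)
  t_df <- if (is.infinite(sq$df_prior)) Inf else sq$df_prior + df
  tstat <- beta / sqrt(sq$var_post * v)
  p <- 2 * stats::pt(-abs(tstat), df = t_df)
  out <- data.frame(gene = rownames(expression), effect = beta, s2 = s2,
                    df = df, s2_post = sq$var_post, t = tstat, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  out
}

count_tables_bound <- function(counts) {
  # upper bound on the number of margin-fixed tables: free cells can each
  # range over at most min(row, col) + 1 values
  r <- nrow(counts); c <- ncol(counts)
  rs <- rowSums(counts); cs <- colSums(counts)
  prod(outer(rs[-r], cs[-c], function(a, b) pmin(a, b) + 1))
}

#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided p-value by probability-mass ordering: the sum of probabilities of
#' all tables with the observed margins whose probability does not exceed the
#' observed table's (Freeman-Halton extension for tables larger than 2 x 2).
#' For large tables where exhaustive enumeration is infeasible a Monte-Carlo
#' estimate can be requested.
#'
#' @param counts matrix of non-negative integer counts.
#' @param monte_carlo use Monte-Carlo estimation for large tables.
#' @param B number of Monte-Carlo replicates.
#' @param max_tables enumeration-size guard for exact r x c tests.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(counts, monte_carlo = FALSE, B = 1e5,
                         max_tables = 1e7) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2 after dropping empty margins")
  big <- !(nrow(counts) == 2L && ncol(counts) == 2L) &&
    count_tables_bound(counts) > max_tables
  if (big && !monte_carlo)
    stop("table too large for exhaustive enumeration; ",
         "call with monte_carlo = TRUE (set a seed for reproducibility)")
  if (big) stats::fisher.test(counts, simulate.p.value = TRUE, B = B)$p.value
  else stats::fisher.test(counts, workspace = 2e7)$p.value
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lower <- if (successes == 0) 0 else max(0, (centre - half) / denom)
  upper <- if (successes == n) 1 else min(1, (centre + half) / denom)
  c(estimate = p, lower = lower, upper = upper)
}

#' Welch two-sample t-test p-value
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return two-sided p-value with unequal-variance (Welch) degrees of freedom.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  stats::t.test(x, y, var.equal = FALSE)$p.value
}
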