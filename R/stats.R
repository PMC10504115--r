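#' Two-sample t test on group means
#'
#' Student's pooled-variance two-sample t test (the default), or Welch's
#' unequal-variance variant. Implemented directly from the textbook formulas;
#' used for comparing per-pair DMC counts between male and female twin pairs.
#'
#' When both groups have zero variance and equal means the statistic is 0 and
#' the p-value 1 (the no-difference convention); unequal means with zero
#' pooled variance give an infinite statistic and p = 0.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch if `TRUE`, use Welch's t with Satterthwaite degrees of
#'   freedom instead of the pooled-variance form.
#' @return list with `statistic`, `df` and `p_value` (two-sided).
#' @export
pooled_t_test <- function(x, y, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    validation_error("pooled_t_test: each group needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    se <- sqrt(se2)
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    df <- nx + ny - 2
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  }
  if (se == 0) {
    t <- if (mx == my) 0 else sign(mx - my) * Inf
    if (is.nan(df)) df <- nx + ny - 2
  } else {
    t <- (mx - my) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

#' Pearson correlation with t-transform p-value
#'
#' Product-moment correlation between two vectors, with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom. Used for the association between pair age and DMC count.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `estimate` (r), `df` and `p_value`.
#' @export
pearson_cor_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) contract_error("pearson_cor_test: length mismatch")
  if (n < 3L)
    validation_error("pearson_cor_test: need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    validation_error("pearson_cor_test: correlation undefined for constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(estimate = r, df = df, p_value = p)
}

#' Pearson chi-square test on a contingency table
#'
#' The classical `sum((O - E)^2 / E)` statistic on an r x c table of counts,
#' with no continuity correction, and p-value from the chi-square
#' distribution on `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param observed numeric matrix of non-negative counts with at least two
#'   rows and two columns; no row or column may sum to zero.
#' @return list with `statistic`, `df`, `p_value` and the `expected` matrix.
#' @export
chisq_stat <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    validation_error("chisq_stat: table must be at least 2 x 2")
  if (any(observed < 0) || any(!is.finite(observed)))
    validation_error("chisq_stat: counts must be finite and non-negative")
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0))
    validation_error("chisq_stat: zero row or column margin; drop empty categories first")
  expected <- outer(rs, cs) / sum(observed)
  stat <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}
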