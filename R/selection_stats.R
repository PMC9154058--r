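# Likelihood-ratio tests for nested site-model comparisons (e.g. M8 vs M8a)
# on externally supplied log-likelihood pairs, and Benjamini-Hochberg false
# discovery rate control.

#' Likelihood-ratio test p-values
#'
#' The statistic is `2 * (lnL_alt - lnL_null)`, clamped at zero (a negative
#' value can only arise from optimizer noise in the upstream model fits and
#' triggers a warning); the p-value is the upper tail of a chi-square
#' distribution with `df` degrees of freedom. For a boundary comparison a
#' 50:50 mixture of chi-square(0) and chi-square(df) is available.
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the null (e.g. M8a) and
#'   alternative (e.g. M8) models; vectors are paired elementwise.
#' @param df Degrees of freedom (default 1).
#' @param mixture If `TRUE`, use the 50:50 boundary mixture null instead of
#'   the plain chi-square.
#' @return Data frame with `lnL_null`, `lnL_alt`, `statistic`, `df`,
#'   `p_value`.
#' @export
lrt_pvalue <- function(lnL_null, lnL_alt, df = 1L, mixture = FALSE) {
  if (any(!is.finite(lnL_null)) || any(!is.finite(lnL_alt))) {
    stop("log-likelihoods must be finite")
  }
  if (length(lnL_null) != length(lnL_alt)) {
    stop("`lnL_null` and `lnL_alt` must have equal length")
  }
  if (df < 1L) stop("`df` must be a positive integer")
  raw <- 2 * (lnL_alt - lnL_null)
  if (any(raw < 0)) {
    warning(sprintf("%d negative LRT statistic(s) clamped to 0", sum(raw < 0)))
  }
  stat <- pmax(raw, 0)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  if (mixture) p <- ifelse(stat == 0, 1, 0.5 * p)
  data.frame(lnL_null = lnL_null, lnL_alt = lnL_alt, statistic = stat,
             df = df, p_value = p)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with the m p-values sorted ascending, find the largest
#' rank `i` with `p(i) <= (i/m) * alpha` and reject hypotheses 1..i.
#' Adjusted p-values are the running minimum of `(m/i) * p(i)` from the
#' largest rank down, capped at 1, reported in the original order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha Target false discovery rate (default 0.05).
#' @return List with `reject` (logical, original order) and `p_adjusted`.
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(list(reject = logical(), p_adjusted = numeric()))
  ord <- order(p)
  ps <- p[ord]
  crit <- seq_len(m) / m * alpha
  below <- which(ps <= crit)
  reject_sorted <- logical(m)
  if (length(below)) reject_sorted[seq_len(max(below))] <- TRUE
  adj_sorted <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  reject <- logical(m); adj <- numeric(m)
  reject[ord] <- reject_sorted
  adj[ord] <- adj_sorted
  list(reject = reject, p_adjusted = adj)
}

#' LRT screen with FDR correction
#'
#' Convenience wrapper: runs [lrt_pvalue()] on a table of log-likelihood
#' pairs and appends Benjamini-Hochberg adjusted p-values and reject flags.
#'
#' @param tab Data frame with columns `domain`, `lnL_null` (or `lnL_M8a`)
#'   and `lnL_alt` (or `lnL_M8`).
#' @param alpha Target false discovery rate.
#' @param df,mixture Passed to [lrt_pvalue()].
#' @return `tab` with columns `statistic`, `p_value`, `p_adjusted`,
#'   `reject` appended.
#' @export
lrt_screen <- function(tab, alpha = 0.05, df = 1L, mixture = FALSE) {
  nn <- names(tab)
  null_col <- if ("lnL_null" %in% nn) "lnL_null" else "lnL_M8a"
  alt_col <- if ("lnL_alt" %in% nn) "lnL_alt" else "lnL_M8"
  if (!all(c(null_col, alt_col) %in% nn)) {
    stop("table must have columns lnL_null/lnL_M8a and lnL_alt/lnL_M8")
  }
  lrt <- lrt_pvalue(tab[[null_col]], tab[[alt_col]], df = df,
                    mixture = mixture)
  bh <- benjamini_hochberg(lrt$p_value, alpha = alpha)
  tab$statistic <- lrt$statistic
  tab$p_value <- lrt$p_value
  tab$p_adjusted <- bh$p_adjusted
  tab$reject <- bh$reject
  tab
}
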