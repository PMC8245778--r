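# Numeric kernel shared by the enrichment and differential-correlation
# screens: average-tie ranking, Spearman/Pearson correlation with a
# t-approximation p-value, and Benjamini-Hochberg FDR.

#' Rank a numeric vector with average ties
#'
#' Assigns ranks `1..n`; tied values receive the arithmetic mean of the ranks
#' they cover (the "average" tie rule used by the Spearman coefficient). The
#' rank sum is always `n(n+1)/2`.
#'
#' @param values Numeric vector, all entries finite.
#' @return Numeric vector of ranks, same length as `values`.
#' @examples
#' rank_average_ties(c(3, 1, 2))        # 3 1 2
#' rank_average_ties(c(1, 2, 2, 5))     # 1 2.5 2.5 4
#' @export
rank_average_ties <- function(values) {
  if (!is.numeric(values) || length(values) < 1L) {
    abort_data("rank_average_ties: input must be a non-empty numeric vector")
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    abort_data(
      "rank_average_ties: non-finite values at positions %s",
      paste(bad, collapse = ", ")
    )
  }
  n <- length(values)
  ord <- order(values)          # stable
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1L]] == values[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

# Pearson coefficient of two equal-length finite vectors; NA if either is
# constant. Internal: inputs already cleaned.
pearson_rho <- function(x, y) {
  sx <- x - mean(x)
  sy <- y - mean(y)
  dx <- sqrt(sum(sx^2))
  dy <- sqrt(sum(sy^2))
  if (dx == 0 || dy == 0) return(NA_real_)
  r <- sum(sx * sy) / (dx * dy)
  max(-1, min(1, r))
}

# Two-sided p for a correlation coefficient via t = rho*sqrt((n-2)/(1-rho^2)),
# n-2 df. |rho| = 1 -> p = 0 by convention.
corr_pvalue <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Correlate two vectors (Spearman or Pearson) with a p-value
#'
#' Spearman is computed as the Pearson coefficient of average-tie ranks. The
#' two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom
#' (adequate at the cohort sizes this pipeline targets); \eqn{|\rho| = 1}
#' yields p = 0 by convention. Missing entries are removed pairwise and the
#' effective `n` is reported. A constant vector (after pairwise removal)
#' yields an explicitly flagged undefined result (`rho = NA`), never a silent
#' zero.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list of class `"correlation_result"`: `rho`, `p_raw`, `n`
#'   (pairwise-complete observations used), `method`, and `ok` (`FALSE` when
#'   the coefficient is undefined, with a `reason`).
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y)) abort_data("correlate: inputs must be numeric")
  if (length(x) != length(y)) {
    abort_data("correlate: length mismatch (%d vs %d)", length(x), length(y))
  }
  if (length(x) < 3L) abort_data("correlate: need at least 3 paired observations")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  res <- list(rho = NA_real_, p_raw = NA_real_, n = n, method = method,
              ok = FALSE, reason = NULL)
  class(res) <- "correlation_result"
  if (n < 3L) { res$reason <- "fewer than 3 complete pairs"; return(res) }
  if (method == "spearman") { x <- rank_average_ties(x); y <- rank_average_ties(y) }
  rho <- pearson_rho(x, y)
  if (is.na(rho)) { res$reason <- "constant vector"; return(res) }
  res$rho <- rho
  res$p_raw <- corr_pvalue(rho, n)
  res$ok <- TRUE
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("%s rho = %.4f, p = %.3g, n = %d\n", x$method, x$rho, x$p_raw, x$n))
  } else {
    cat(sprintf("%s correlation undefined (%s), n = %d\n", x$method, x$reason, x$n))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and restored to
#' the input order. Missing entries are preserved as missing and do not count
#' toward `m`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) abort_data("bh_adjust: input must be numeric")
  obs <- which(!is.na(p_values))
  p <- p_values[obs]
  if (any(p < 0 | p > 1)) abort_data("bh_adjust: p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)                 # largest first
    q <- pmin(1, cummin((m / seq(m, 1)) * p[o]))     # running min from the top rank
    out[obs][o] <- q
  }
  out
}
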