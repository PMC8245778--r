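# Marker-guided endothelial-enrichment screen: correlate every gene with the
# EC marker panel across samples, average the coefficients, rank, and call
# genes above the mean-correlation threshold "EC-enriched".

#' Endothelial marker panel
#'
#' @param marker_ids Character vector of at least 2 unique gene ids
#'   (default `c("CDH5", "CLDN5", "VWF")`, the canonical vascular
#'   endothelial markers).
#' @return Character vector of class `"marker_panel"`.
#' @export
marker_panel <- function(marker_ids = c("CDH5", "CLDN5", "VWF")) {
  if (!is.character(marker_ids) || length(marker_ids) < 2L) {
    abort_config("marker_panel: need at least 2 marker gene ids")
  }
  if (anyDuplicated(marker_ids)) {
    abort_config("marker_panel: duplicate marker id '%s'",
                 marker_ids[duplicated(marker_ids)][1L])
  }
  structure(marker_ids, class = "marker_panel")
}

#' Per-gene marker-correlation profile
#'
#' For every gene in the matrix (markers included), computes the correlation
#' with each marker gene and the arithmetic mean over the panel. A marker's
#' self-correlation (rho = 1) is included in its own mean, so markers sit at
#' the top of the ranking by construction. Genes whose correlation with any
#' marker is undefined (zero variance, or too few complete pairs) are set
#' aside in a `dropped` table with a reason code rather than silently
#' removed. The per-gene summary p-value combines the per-marker two-sided
#' p-values (Fisher's method by default, minimum-p as an alternative).
#'
#' @param expr Numeric gene x sample matrix with dimnames.
#' @param panel A [marker_panel()] whose genes must all be rows of `expr`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param summary_p `"fisher"` (default) or `"min"`.
#' @return List of class `"marker_profile"`: `scores` (data.frame with
#'   `gene_id`, one `rho_<marker>` column per marker, `mean_corr`, `p_raw`,
#'   `n`), `dropped` (gene_id, reason), plus `panel`, `method`, `n_samples`.
#' @export
marker_correlation_profile <- function(expr, panel = marker_panel(),
                                       method = c("spearman", "pearson"),
                                       summary_p = c("fisher", "min")) {
  method <- match.arg(method)
  summary_p <- match.arg(summary_p)
  check_expression(expr)
  if (ncol(expr) < 3L) abort_data("marker_correlation_profile: need at least 3 samples")
  missing_markers <- setdiff(unclass(panel), rownames(expr))
  if (length(missing_markers)) {
    abort_config("marker '%s' not found in the expression matrix", missing_markers[1L])
  }
  markers <- unclass(panel)
  genes <- rownames(expr)
  k <- length(markers)
  rho <- matrix(NA_real_, nrow = length(genes), ncol = k,
                dimnames = list(genes, markers))
  pmat <- rho
  nmin <- rep(ncol(expr), length(genes))
  for (g in seq_along(genes)) {
    for (m in seq_len(k)) {
      cr <- correlate(expr[g, ], expr[markers[m], ], method = method)
      rho[g, m] <- cr$rho
      pmat[g, m] <- cr$p_raw
      nmin[g] <- min(nmin[g], cr$n)
    }
  }
  undef <- rowSums(is.na(rho)) > 0
  mean_corr <- rowMeans(rho)
  p_raw <- if (summary_p == "fisher") {
    stats::pchisq(-2 * rowSums(log(pmat)), df = 2 * k, lower.tail = FALSE)
  } else {
    apply(pmat, 1, min)
  }
  scores <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (m in seq_len(k)) scores[[paste0("rho_", markers[m])]] <- rho[, m]
  scores$mean_corr <- mean_corr
  scores$p_raw <- p_raw
  scores$n <- nmin
  dropped <- data.frame(gene_id = genes[undef],
                        reason = rep("zero variance or insufficient pairs", sum(undef)),
                        stringsAsFactors = FALSE)
  structure(list(scores = scores[!undef, , drop = FALSE], dropped = dropped,
                 panel = markers, method = method, n_samples = ncol(expr)),
            class = "marker_profile")
}

#' Screen the profile for EC-enriched genes
#'
#' Applies the mean-correlation cutoff (strict `>`, default 0.3), assigns
#' ranks by descending mean correlation (rank 1 = most enriched; ties broken
#' lexicographically by gene id so ranks are reproducible), and adjusts the
#' per-gene summary p-values by Benjamini-Hochberg over all scored genes.
#'
#' @param profile A [marker_correlation_profile()] result.
#' @param threshold Enrichment cutoff on the mean correlation, in (-1, 1).
#' @return List of class `"enrichment_result"`: `scores` (profile columns
#'   plus `fdr`, `rank`, `enriched`, ordered by rank), `threshold`,
#'   `dropped`, `panel`, `method`.
#' @export
enrichment_screen <- function(profile, threshold = 0.3) {
  if (!inherits(profile, "marker_profile")) abort_data("enrichment_screen: not a marker_profile")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= -1 || threshold >= 1) {
    abort_config("enrichment_screen: 'threshold' must lie in (-1, 1)")
  }
  sc <- profile$scores
  if (!nrow(sc)) abort_data("enrichment_screen: empty profile (no scorable genes)")
  sc$fdr <- bh_adjust(sc$p_raw)
  ord <- order(-sc$mean_corr, sc$gene_id)
  sc <- sc[ord, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  sc$enriched <- sc$mean_corr > threshold
  rownames(sc) <- NULL
  structure(list(scores = sc, threshold = threshold, dropped = profile$dropped,
                 panel = profile$panel, method = profile$method),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d scored genes, %d enriched (mean corr > %g), %d dropped\n",
              nrow(x$scores), sum(x$scores$enriched), x$threshold, nrow(x$dropped)))
  print(utils::head(x$scores[, c("gene_id", "mean_corr", "fdr", "rank", "enriched")], 10))
  invisible(x)
}

#' Gene ids called EC-enriched
#' @param screen An [enrichment_screen()] result.
#' @return Character vector in rank order.
#' @export
enriched_genes <- function(screen) {
  if (!inherits(screen, "enrichment_result")) abort_data("enriched_genes: not an enrichment_result")
  screen$scores$gene_id[screen$scores$enriched]
}

#' Frequency distribution of mean marker correlations
#'
#' Bins the per-gene mean correlation into half-open intervals `[lo, lo+w)`
#' whose edges are multiples of the bin width, covering [-1, 1]. Counts sum
#' to the number of scored genes.
#'
#' @param profile A [marker_correlation_profile()] or [enrichment_screen()]
#'   result.
#' @param bin_width Positive bin width (default 0.05).
#' @return data.frame with `bin_lo`, `bin_hi`, `count` (all grid bins,
#'   including empty ones).
#' @export
frequency_distribution <- function(profile, bin_width = 0.05) {
  if (inherits(profile, "enrichment_result")) {
    x <- profile$scores$mean_corr
  } else if (inherits(profile, "marker_profile")) {
    x <- profile$scores$mean_corr
  } else {
    abort_data("frequency_distribution: not a marker_profile or enrichment_result")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0) {
    abort_config("frequency_distribution: 'bin_width' must be positive")
  }
  idx <- floor(x / bin_width)              # definitional half-open binning
  lo_grid <- seq.int(floor(-1 / bin_width), max(floor(1 / bin_width), max(idx)))
  counts <- vapply(lo_grid, function(i) sum(idx == i), integer(1))
  data.frame(bin_lo = lo_grid * bin_width,
             bin_hi = (lo_grid + 1) * bin_width,
             count = counts)
}
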