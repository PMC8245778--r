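# Imaging phenotype and differential-correlation scoring: compute the
# enhancing-volume fraction EV/CV per tumor, dichotomize the cohort into its
# top-k and bottom-k extremes, and score every EC-enriched gene by the
# difference of its group-wise mean marker correlation (CE-high minus
# CE-low).

#' Compute segmentation features (CV and EV/CV ratio)
#'
#' `CV = EV + NV` exactly; `ratio = EV / CV`. Volumes must be non-negative
#' and finite; samples with `CV = 0` are rejected by name.
#'
#' @param volumes data.frame with `sample_id`, `EV`, `NV`.
#' @return data.frame of class `"segmentation_features"` with `sample_id`,
#'   `EV`, `NV`, `CV`, `ratio`.
#' @export
compute_segmentation_features <- function(volumes) {
  need <- c("sample_id", "EV", "NV")
  if (!is.data.frame(volumes) || !all(need %in% names(volumes))) {
    abort_data("compute_segmentation_features: need columns sample_id, EV, NV")
  }
  if (anyDuplicated(volumes$sample_id)) abort_data("duplicate sample ids in volume table")
  ev <- volumes$EV; nv <- volumes$NV
  bad <- !is.finite(ev) | !is.finite(nv) | ev < 0 | nv < 0
  if (any(bad)) {
    abort_data("negative or non-finite volume for sample '%s'", volumes$sample_id[bad][1L])
  }
  cv <- ev + nv
  if (any(cv == 0)) {
    abort_data("zero complete tumor volume for sample '%s'", volumes$sample_id[cv == 0][1L])
  }
  out <- data.frame(sample_id = as.character(volumes$sample_id), EV = ev, NV = nv,
                    CV = cv, ratio = ev / cv, stringsAsFactors = FALSE)
  class(out) <- c("segmentation_features", "data.frame")
  out
}

#' Dichotomize samples into the EV/CV extremes
#'
#' The `k` samples with the highest EV/CV ratio become the CE-high group, the
#' `k` lowest the CE-low group, everyone else is unassigned. Ties at a group
#' boundary are broken deterministically by ascending sample id; in the
#' degenerate case `n = 2k` with a tie block spanning the boundary, CE-low
#' claims the contested sample and CE-high takes the next candidate.
#'
#' @param features A [compute_segmentation_features()] table.
#' @param k Extremes size (default 20).
#' @return data.frame of class `"group_assignment"` with `sample_id`,
#'   `ratio`, `group` in `{CE-high, CE-low, unassigned}`; attribute `k`.
#' @export
dichotomize_extremes <- function(features, k = 20L) {
  if (!inherits(features, "segmentation_features")) {
    abort_data("dichotomize_extremes: not a segmentation_features table")
  }
  keep <- is.finite(features$ratio)
  dropped <- sum(!keep)
  if (dropped) message(sprintf("dichotomize_extremes: excluding %d sample(s) with missing segmentation", dropped))
  features <- features[keep, , drop = FALSE]
  n <- nrow(features)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort_config("dichotomize_extremes: 'k' must be a positive integer")
  if (n < 2L * k) {
    abort_config("dichotomize_extremes: need n >= 2k samples (n = %d, k = %d)", n, k)
  }
  id <- features$sample_id
  lo <- order(features$ratio, id)[seq_len(k)]
  # when n = 2k a tie spanning the boundary can qualify a sample for both
  # extremes; CE-low claims it (the ties-go-low convention), CE-high takes
  # the next candidate in its own (descending ratio, ascending id) order
  hi <- setdiff(order(-features$ratio, id), lo)[seq_len(k)]
  group <- rep("unassigned", n)
  group[hi] <- "CE-high"
  group[lo] <- "CE-low"
  out <- data.frame(sample_id = id, ratio = features$ratio, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", "data.frame")
  attr(out, "k") <- k
  out
}

# mean marker correlation of each gene within one sample subset, same
# convention as the full-cohort screen (marker self-correlation included)
group_mean_marker_corr <- function(expr, panel, genes, sample_ids, method) {
  sub <- expr[, sample_ids, drop = FALSE]
  markers <- unclass(panel)
  vapply(genes, function(g) {
    rhos <- vapply(markers, function(m) correlate(sub[g, ], sub[m, ], method = method)$rho,
                   numeric(1))
    mean(rhos)   # NA if any marker correlation is undefined in this group
  }, numeric(1))
}

#' Differential correlation score between CE-high and CE-low tumors
#'
#' For each EC-enriched gene, the mean marker correlation is recomputed from
#' scratch within the CE-high samples and within the CE-low samples (same
#' convention as the full-cohort screen, marker self-correlation included);
#' the differential score is `delta = corr_high - corr_low`. Genes constant
#' within either group get a missing group correlation and are reported
#' unclassifiable with a reason code. Classification against the default
#' thresholds is attached; see [classify_ce_association()] to re-threshold.
#'
#' @param expr Gene x sample expression matrix.
#' @param panel A [marker_panel()].
#' @param ec_genes Either a character vector of gene ids or an
#'   [enrichment_screen()] result (then the enriched set is scored and the
#'   full-cohort `ec_rank` is carried through).
#' @param groups A [dichotomize_extremes()] assignment (or any data.frame
#'   with `sample_id` and `group` in `{CE-high, CE-low}`), or a list
#'   `list(high = ids, low = ids)` of sample ids — the two lists may overlap,
#'   which is occasionally useful for null checks.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param up_threshold,down_threshold Classification cutoffs, defaults 0.1
#'   and -0.4.
#' @return data.frame of class `"differential_score_table"`: `gene_id`,
#'   `corr_high`, `corr_low`, `delta`, `ce_class`, `ec_rank`, `n_high`,
#'   `n_low`, `reason`.
#' @export
differential_correlation_score <- function(expr, panel, ec_genes, groups,
                                           method = c("spearman", "pearson"),
                                           up_threshold = 0.1,
                                           down_threshold = -0.4) {
  method <- match.arg(method)
  check_expression(expr)
  ec_rank <- NULL
  if (inherits(ec_genes, "enrichment_result")) {
    sc <- ec_genes$scores
    ec_rank <- stats::setNames(sc$rank, sc$gene_id)
    ec_genes <- sc$gene_id[sc$enriched]
  }
  if (!is.character(ec_genes) || !length(ec_genes)) {
    abort_data("differential_correlation_score: empty EC gene set")
  }
  missing_genes <- setdiff(c(ec_genes, unclass(panel)), rownames(expr))
  if (length(missing_genes)) {
    abort_data("gene '%s' not found in the expression matrix", missing_genes[1L])
  }
  if (is.list(groups) && !is.data.frame(groups) &&
      all(c("high", "low") %in% names(groups))) {
    hi_ids <- as.character(groups$high)
    lo_ids <- as.character(groups$low)
  } else if (is.data.frame(groups) && all(c("sample_id", "group") %in% names(groups))) {
    hi_ids <- groups$sample_id[groups$group == "CE-high"]
    lo_ids <- groups$sample_id[groups$group == "CE-low"]
  } else {
    abort_data("differential_correlation_score: groups need sample_id/group columns or high/low lists")
  }
  missing_samples <- setdiff(c(hi_ids, lo_ids), colnames(expr))
  if (length(missing_samples)) {
    abort_data("sample '%s' not found in the expression matrix", missing_samples[1L])
  }
  if (length(hi_ids) < 3L || length(lo_ids) < 3L) {
    abort_data("differential_correlation_score: each group needs >= 3 samples (got %d and %d)",
               length(hi_ids), length(lo_ids))
  }
  corr_high <- group_mean_marker_corr(expr, panel, ec_genes, hi_ids, method)
  corr_low <- group_mean_marker_corr(expr, panel, ec_genes, lo_ids, method)
  out <- data.frame(gene_id = ec_genes,
                    corr_high = unname(corr_high),
                    corr_low = unname(corr_low),
                    delta = unname(corr_high - corr_low),
                    stringsAsFactors = FALSE)
  out$ec_rank <- if (is.null(ec_rank)) NA_integer_ else unname(ec_rank[ec_genes])
  out$n_high <- length(hi_ids)
  out$n_low <- length(lo_ids)
  out$reason <- ifelse(is.na(out$delta), "zero variance within a group", "")
  class(out) <- c("differential_score_table", "data.frame")
  classify_ce_association(out, up_threshold = up_threshold,
                          down_threshold = down_threshold)
}

#' Classify genes by their differential correlation score
#'
#' Strict thresholds: `delta > up_threshold` is CE-high-associated,
#' `delta < down_threshold` is CE-low-associated, anything in between
#' (boundaries included) is unclassified. Idempotent; depends only on
#' `delta` and the thresholds.
#'
#' @param table A [differential_correlation_score()] table.
#' @param up_threshold,down_threshold Cutoffs with
#'   `down_threshold < up_threshold` (defaults 0.1, -0.4).
#' @return The table with `ce_class` recomputed.
#' @export
classify_ce_association <- function(table, up_threshold = 0.1, down_threshold = -0.4) {
  if (!inherits(table, "differential_score_table")) {
    abort_data("classify_ce_association: not a differential_score_table")
  }
  stopifnot_scalar_number(up_threshold, "up_threshold", -2, 2)
  stopifnot_scalar_number(down_threshold, "down_threshold", -2, 2)
  if (down_threshold >= up_threshold) {
    abort_config("classify_ce_association: down_threshold (%g) must be < up_threshold (%g)",
                 down_threshold, up_threshold)
  }
  d <- table$delta
  cls <- rep("unclassified", nrow(table))
  cls[!is.na(d) & d > up_threshold] <- "CE-high-associated"
  cls[!is.na(d) & d < down_threshold] <- "CE-low-associated"
  cls[is.na(d)] <- "unclassifiable"
  table$ce_class <- cls
  attr(table, "up_threshold") <- up_threshold
  attr(table, "down_threshold") <- down_threshold
  table
}
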