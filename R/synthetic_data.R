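# Synthetic bulk-mixture generator. Emulates a tumor cohort whose bulk
# transcriptome is a convex mixture of one endothelial compartment plus
# several non-endothelial cell types; a latent contrast-enhancement level
# drives the imaging phenotype, a subset of endothelial genes is expressed
# only in the enhancing (or only in the non-enhancing) extreme, and survival
# is tied to the enhancement phenotype. Everything is seeded and carries
# planted ground truth for recovery testing.

MARKER_IDS <- c("CDH5", "CLDN5", "VWF")

#' Configuration for the synthetic mixture generator
#'
#' Defaults emulate a 128-case bulk GBM cohort: 2000 genes of which 3 are the
#' endothelial marker panel, 150 are constitutively endothelial, 40 are
#' endothelial only in strongly-enhancing tumors, 40 only in weakly-enhancing
#' tumors, and the rest are background genes loading on one of 3 non-EC cell
#' types. The endothelial fraction per sample is uniform on
#' `ec_fraction_range` and independent of the enhancement level, so
#' "EC-enriched" and "CE-associated" stay separable signals.
#'
#' @param n_samples Number of samples (default 128).
#' @param n_genes Total gene count including the 3 markers (default 2000).
#' @param n_ec_constitutive Genes always expressed in EC (default 150).
#' @param n_ce_high_conditional Genes expressed in EC only in CE-high samples
#'   (top tertile of the latent enhancement level; default 40).
#' @param n_ce_low_conditional Symmetric for the bottom tertile (default 40).
#' @param n_cell_types Number of non-EC cell types (default 3).
#' @param ec_fraction_range Range of the per-sample EC fraction, within (0,1)
#'   (default `c(0.01, 0.15)`); equal bounds are allowed as a degenerate
#'   fixed-fraction design.
#' @param ec_signal Fold-expression of an EC gene inside EC vs elsewhere
#'   (default 50).
#' @param noise_sd SD of additive Gaussian noise on the log2 scale (default 0.3).
#' @param hazard_ratio True CE-high vs CE-low hazard ratio (default 1.8).
#' @param censor_fraction Target censoring proportion (default 0.3).
#' @param seed Integer RNG seed (default 1).
#' @return Validated list of class `"mixture_config"`.
#' @export
mixture_config <- function(n_samples = 128L, n_genes = 2000L,
                           n_ec_constitutive = 150L,
                           n_ce_high_conditional = 40L,
                           n_ce_low_conditional = 40L,
                           n_cell_types = 3L,
                           ec_fraction_range = c(0.01, 0.15),
                           ec_signal = 50, noise_sd = 0.3,
                           hazard_ratio = 1.8, censor_fraction = 0.3,
                           seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_ec_constitutive = as.integer(n_ec_constitutive),
              n_ce_high_conditional = as.integer(n_ce_high_conditional),
              n_ce_low_conditional = as.integer(n_ce_low_conditional),
              n_cell_types = as.integer(n_cell_types),
              ec_fraction_range = as.numeric(ec_fraction_range),
              ec_signal = ec_signal, noise_sd = noise_sd,
              hazard_ratio = hazard_ratio, censor_fraction = censor_fraction,
              seed = as.integer(seed))
  validate_mixture_config(cfg)
  class(cfg) <- "mixture_config"
  cfg
}

validate_mixture_config <- function(cfg) {
  pos <- c("n_samples", "n_genes", "n_cell_types")
  for (f in pos) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) abort_config("mixture_config: '%s' must be a positive count", f)
  }
  nonneg <- c("n_ec_constitutive", "n_ce_high_conditional", "n_ce_low_conditional")
  for (f in nonneg) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) abort_config("mixture_config: '%s' must be a non-negative count", f)
  }
  planted <- cfg$n_ec_constitutive + cfg$n_ce_high_conditional + cfg$n_ce_low_conditional
  if (planted + length(MARKER_IDS) > cfg$n_genes) {
    abort_config("mixture_config: 'n_genes' too small for %d planted genes plus %d markers",
                 planted, length(MARKER_IDS))
  }
  rng <- cfg$ec_fraction_range
  if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] <= 0 || rng[2] >= 1 || rng[1] > rng[2]) {
    abort_config("mixture_config: 'ec_fraction_range' must be [low, high] within (0, 1) with low <= high")
  }
  if (!is.finite(cfg$ec_signal) || cfg$ec_signal <= 0) abort_config("mixture_config: 'ec_signal' must be > 0")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0) abort_config("mixture_config: 'noise_sd' must be >= 0")
  if (!is.finite(cfg$hazard_ratio) || cfg$hazard_ratio <= 0) abort_config("mixture_config: 'hazard_ratio' must be > 0")
  if (!is.finite(cfg$censor_fraction) || cfg$censor_fraction < 0 || cfg$censor_fraction >= 1) {
    abort_config("mixture_config: 'censor_fraction' must be in [0, 1)")
  }
  if (is.na(cfg$seed)) abort_config("mixture_config: 'seed' must be an integer")
  invisible(cfg)
}

# One global seed spawns independent named sub-streams so that changing one
# block's parameters never perturbs the draws of another block.
derive_substreams <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("latent", "expression", "segmentation", "clinical")
  s
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Generative model, per sample \eqn{s}: latent enhancement level
#' \eqn{z_s \sim U(0,1)}; EC fraction \eqn{f_s \sim U} on
#' `ec_fraction_range`, independent of \eqn{z}; the remaining mass is split
#' across non-EC cell types by a symmetric Dirichlet. Marker and constitutive
#' EC genes express `ec_signal` in EC and 1 elsewhere; conditional genes are
#' gated by the tertile of \eqn{z_s}; each background gene loads `ec_signal`
#' on one random non-EC cell type. Observed expression is
#' \eqn{\log_2(1 + \sum_c f_{c,s} S_{g,c,s}) + N(0, \sigma^2)}.
#' Segmentation: EV/CV ratio \eqn{r_s = } clamp\eqn{(z_s + N(0,0.05),
#' 0.001, 0.999)}, total volume log-normal, EV \eqn{= r_s} CV. Clinical:
#' exponential survival with hazard multiplied by `hazard_ratio` when
#' \eqn{r_s} is above the cohort median, uniform censoring tuned to
#' `censor_fraction`, age truncated-normal (60, 10) on [18, 90], and the
#' mesenchymal subtype label drawn with probability \eqn{0.25 + 0.35 z_s}.
#'
#' @param config A [mixture_config()].
#' @return List of class `"synthetic_dataset"` with elements `expression`
#'   (gene x sample matrix), `segmentation` (sample_id, EV, NV),
#'   `clinical` (sample_id, os_time, os_event, age, subtype), `truth`
#'   (`genes`: gene_id, gene_class; `samples`: sample_id, ce_latent,
#'   ec_fraction, true_group) and `config`.
#' @export
generate_dataset <- function(config = mixture_config()) {
  validate_mixture_config(config)
  streams <- derive_substreams(config$seed)
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  # --- latent stream: enhancement level, cell-type fractions -------------
  set.seed(streams[["latent"]])
  z <- stats::runif(n)
  f <- stats::runif(n, config$ec_fraction_range[1], config$ec_fraction_range[2])
  w <- matrix(stats::rgamma(n * config$n_cell_types, shape = 1), nrow = config$n_cell_types)
  w <- sweep(w, 2, colSums(w), "/")               # symmetric Dirichlet
  w <- sweep(w, 2, 1 - f, "*")                    # non-EC mass
  q <- stats::quantile(z, c(1/3, 2/3), names = FALSE, type = 7)
  gate_high <- z > q[2]                           # top tertile of z
  gate_low <- z < q[1]                            # bottom tertile
  true_group <- ifelse(gate_high, "CE-high", ifelse(gate_low, "CE-low", "intermediate"))

  # --- gene layout --------------------------------------------------------
  n_bg <- config$n_genes - length(MARKER_IDS) - config$n_ec_constitutive -
    config$n_ce_high_conditional - config$n_ce_low_conditional
  gene_class <- c(rep("marker", length(MARKER_IDS)),
                  rep("ec_constitutive", config$n_ec_constitutive),
                  rep("ce_high_conditional", config$n_ce_high_conditional),
                  rep("ce_low_conditional", config$n_ce_low_conditional),
                  rep("background", n_bg))
  gene_ids <- c(MARKER_IDS,
                sprintf("ECG%04d", seq_len(config$n_ec_constitutive)),
                sprintf("CEH%04d", seq_len(config$n_ce_high_conditional)),
                sprintf("CEL%04d", seq_len(config$n_ce_low_conditional)),
                sprintf("BG%05d", seq_len(n_bg)))

  # --- expression stream --------------------------------------------------
  set.seed(streams[["expression"]])
  sig <- config$ec_signal
  bg_celltype <- if (n_bg) sample.int(config$n_cell_types, n_bg, replace = TRUE) else integer(0)
  mix <- matrix(0, nrow = config$n_genes, ncol = n, dimnames = list(gene_ids, sample_ids))
  ec_rows <- gene_class %in% c("marker", "ec_constitutive")
  # always-EC genes: sig in EC, 1 elsewhere -> f*sig + (1-f)
  mix[ec_rows, ] <- matrix(f * sig + (1 - f), nrow = sum(ec_rows), ncol = n, byrow = TRUE)
  cond_val <- function(gate) f * ifelse(gate, sig, 1) + (1 - f)
  hi_rows <- gene_class == "ce_high_conditional"
  if (any(hi_rows)) mix[hi_rows, ] <- matrix(cond_val(gate_high), nrow = sum(hi_rows), ncol = n, byrow = TRUE)
  lo_rows <- gene_class == "ce_low_conditional"
  if (any(lo_rows)) mix[lo_rows, ] <- matrix(cond_val(gate_low), nrow = sum(lo_rows), ncol = n, byrow = TRUE)
  if (n_bg) {
    # background gene: sig on one non-EC cell type of fraction w_c, 1 elsewhere
    bg_vals <- 1 + (sig - 1) * w[bg_celltype, , drop = FALSE]
    mix[gene_class == "background", ] <- bg_vals
  }
  expr <- log2(1 + mix)
  if (config$noise_sd > 0) {
    expr <- expr + matrix(stats::rnorm(length(expr), sd = config$noise_sd),
                          nrow = nrow(expr))
  }

  # --- segmentation stream ------------------------------------------------
  set.seed(streams[["segmentation"]])
  r <- pmin(pmax(z + stats::rnorm(n, sd = 0.05), 0.001), 0.999)
  cv <- stats::rlnorm(n, meanlog = log(3e4), sdlog = 0.4)  # arbitrary mm^3-like scale
  ev <- r * cv
  nv <- cv - ev
  segmentation <- data.frame(sample_id = sample_ids, EV = ev, NV = nv,
                             stringsAsFactors = FALSE)

  # --- clinical stream ----------------------------------------------------
  set.seed(streams[["clinical"]])
  h0 <- log(2) / 400                                # median OS ~400 days at baseline
  rate <- h0 * config$hazard_ratio^(r > stats::median(r))
  t_event <- stats::rexp(n, rate = rate)
  if (config$censor_fraction > 0) {
    # P(C < T) for C ~ U(0, u), T ~ Exp(rate): (1 - exp(-rate*u)) / (rate*u);
    # tune u so the cohort-average censoring matches the target.
    target <- config$censor_fraction
    cens_prob <- function(u) mean((1 - exp(-rate * u)) / (rate * u)) - target
    u <- stats::uniroot(cens_prob, lower = 1e-6, upper = 1e9, tol = 1e-8)$root
    c_time <- stats::runif(n, 0, u)
  } else {
    c_time <- rep(Inf, n)
  }
  os_time <- pmin(t_event, c_time)
  os_event <- as.integer(t_event <= c_time)
  age <- stats::qnorm(stats::runif(n, stats::pnorm(18, 60, 10), stats::pnorm(90, 60, 10)), 60, 10)
  p_mes <- 0.25 + 0.35 * z
  is_mes <- stats::runif(n) < p_mes
  other <- sample(c("proneural", "classical", "neural"), n, replace = TRUE)
  subtype <- ifelse(is_mes, "mesenchymal", other)
  clinical <- data.frame(sample_id = sample_ids, os_time = os_time,
                         os_event = os_event, age = age, subtype = subtype,
                         stringsAsFactors = FALSE)

  truth <- list(
    genes = data.frame(gene_id = gene_ids, gene_class = gene_class,
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_ids, ce_latent = z, ec_fraction = f,
                         true_group = true_group, stringsAsFactors = FALSE)
  )
  structure(list(expression = expr, segmentation = segmentation,
                 clinical = clinical, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d samples (seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$config$seed))
  cat("  gene classes:", paste(sprintf("%s=%d", names(table(x$truth$genes$gene_class)),
                                       table(x$truth$genes$gene_class)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic dataset as TSV files
#'
#' Writes `expression.tsv`, `segmentation.tsv`, `clinical.tsv` plus the two
#' ground-truth tables `truth_genes.tsv` and `truth_samples.tsv`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_dataset")) abort_data("write_dataset: not a synthetic_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    segmentation = file.path(dir, "segmentation.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv")
  )
  write_expression(dataset$expression, paths[["expression"]])
  write_tsv(dataset$segmentation, paths[["segmentation"]])
  write_tsv(dataset$clinical, paths[["clinical"]])
  write_tsv(dataset$truth$genes, paths[["truth_genes"]])
  write_tsv(dataset$truth$samples, paths[["truth_samples"]])
  invisible(paths)
}
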