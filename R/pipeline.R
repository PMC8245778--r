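# End-to-end pipeline: enrichment screen -> CE association -> survival,
# with TSV/JSON outputs and a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    expression = NULL, segmentation = NULL, clinical = NULL, out_dir = ".",
    marker_ids = c("CDH5", "CLDN5", "VWF"),
    method = "spearman",
    enrichment_threshold = 0.3,
    bin_width = 0.05,
    k = 20L,
    up_threshold = 0.1,
    down_threshold = -0.4,
    age_cutoff = 60,
    seed = 1L,
    # simulate-only knobs (forwarded to mixture_config)
    n_samples = 128L, n_genes = 2000L, n_ec_constitutive = 150L,
    n_ce_high_conditional = 40L, n_ce_low_conditional = 40L,
    n_cell_types = 3L, ec_fraction_range = c(0.01, 0.15),
    ec_signal = 50, noise_sd = 0.3, hazard_ratio = 1.8, censor_fraction = 0.3
  )
}

#' Assemble and validate a pipeline configuration
#'
#' Flat key-value configuration mirrored by the JSON config file of the CLI.
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param ... Overrides of the defaults (paths `expression`, `segmentation`,
#'   `clinical`, `out_dir`; analysis knobs `marker_ids`, `method`,
#'   `enrichment_threshold`, `bin_width`, `k`, `up_threshold`,
#'   `down_threshold`, `age_cutoff`, `seed`; generator knobs as in
#'   [mixture_config()]).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) abort_config("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$method <- match.arg(cfg$method, c("spearman", "pearson"))
  stopifnot_scalar_number(cfg$enrichment_threshold, "enrichment_threshold", -1, 1)
  stopifnot_scalar_number(cfg$bin_width, "bin_width", 1e-6, 2)
  stopifnot_scalar_number(cfg$k, "k", 1, Inf)
  stopifnot_scalar_number(cfg$up_threshold, "up_threshold", -2, 2)
  stopifnot_scalar_number(cfg$down_threshold, "down_threshold", -2, 2)
  if (cfg$down_threshold >= cfg$up_threshold) {
    abort_config("down_threshold must be < up_threshold")
  }
  stopifnot_scalar_number(cfg$age_cutoff, "age_cutoff", 0, 150)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a flat JSON file
#' @param path JSON file with keys as in [pipeline_config()].
#' @return `"pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: %s", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_config("config file %s is not valid JSON: %s",
                                                   path, conditionMessage(e)))
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Executes the enrichment screen, the CE-association scoring and the
#' survival analyses in order on the three input tables, and writes
#' `enrichment.tsv`, `histogram.tsv`, `diff_scores.tsv`, `km_<group>.tsv`,
#' `survival_report.json` and `manifest.json` into `config$out_dir`.
#' Re-running with identical inputs and configuration reproduces
#' byte-identical outputs (no timestamps are embedded).
#'
#' @param config A [pipeline_config()] with the three input paths set, or a
#'   path to a JSON config.
#' @return Invisibly, a list with the in-memory stage results and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) abort_config("run_pipeline: not a pipeline_config")
  for (f in c("expression", "segmentation", "clinical")) {
    if (is.null(config[[f]])) abort_config("run_pipeline: config lacks input path '%s'", f)
    if (!file.exists(config[[f]])) abort_data("run_pipeline: %s file not found: %s", f, config[[f]])
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)

  expr <- read_expression(config$expression)
  volumes <- read_segmentation(config$segmentation)
  clinical <- read_clinical(config$clinical)

  # sample-id joins are set-based, hence order-independent
  shared <- intersect(intersect(colnames(expr), volumes$sample_id), clinical$sample_id)
  if (length(shared) < 3L) abort_data("run_pipeline: fewer than 3 samples shared by the three tables")
  shared <- sort(shared)
  expr <- expr[, shared, drop = FALSE]
  volumes <- volumes[match(shared, volumes$sample_id), , drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]

  panel <- marker_panel(config$marker_ids)

  # stage 1: EC-enrichment screen
  profile <- marker_correlation_profile(expr, panel, method = config$method)
  screen <- enrichment_screen(profile, threshold = config$enrichment_threshold)
  hist_tab <- frequency_distribution(screen, bin_width = config$bin_width)
  write_tsv(screen$scores, out("enrichment.tsv"))
  write_tsv(hist_tab, out("histogram.tsv"))
  if (nrow(screen$dropped)) write_tsv(screen$dropped, out("enrichment_dropped.tsv"))

  # stage 2: CE association on the EV/CV extremes
  features <- compute_segmentation_features(volumes)
  extremes <- dichotomize_extremes(features, k = config$k)
  diff_tab <- differential_correlation_score(expr, panel, screen, extremes,
                                             method = config$method,
                                             up_threshold = config$up_threshold,
                                             down_threshold = config$down_threshold)
  write_tsv(as.data.frame(diff_tab), out("diff_scores.tsv"))

  # stage 3: survival by median EV/CV split, age subgroups, subtype contrast
  comparison <- survival_comparison(features, clinical)
  if (!isTRUE(comparison$evaluable)) {
    abort_data("run_pipeline: survival stage not evaluable (%s)", comparison$reason)
  }
  for (grp in names(comparison$km)) {
    write_tsv(comparison$km[[grp]]$table, out(sprintf("km_%s.tsv", grp)))
  }
  split <- median_split(features)
  covar <- data.frame(
    ce_high = as.numeric(split$group[match(clinical$sample_id, split$sample_id)] == "CE-high"),
    age = clinical$age
  )
  cox <- tryCatch(cox_fit(clinical$os_time, clinical$os_event, covar),
                  vascreen_data_error = function(e) NULL)
  subgroups <- age_subgroup_analysis(features, clinical, cutoff = config$age_cutoff)
  subtype <- if (sum(clinical$subtype == "mesenchymal") >= 2 &&
                 sum(!clinical$subtype %in% c("mesenchymal", "unknown")) >= 2) {
    compare_ratio_by_subtype(features, clinical)
  } else NULL

  strip_comparison <- function(cmp) {
    if (!isTRUE(cmp$evaluable)) return(cmp)
    list(evaluable = TRUE, cutoff = cmp$cutoff, n = as.list(cmp$n),
         logrank = cmp$logrank[c("chi2", "p", "observed", "expected")],
         km_median = lapply(cmp$km, function(k) k$median))
  }
  report <- list(
    n_samples = length(shared),
    median_cutoff = comparison$cutoff,
    logrank = comparison$logrank[c("chi2", "p", "observed", "expected", "n_a", "n_b")],
    km_median = lapply(comparison$km, function(k) k$median),
    cox = if (is.null(cox)) "not fitted (degenerate design)" else cox$table,
    age_subgroups = list(younger = strip_comparison(subgroups$younger),
                         older = strip_comparison(subgroups$older),
                         cutoff = subgroups$cutoff),
    subtype = if (is.null(subtype)) "not evaluable" else unclass(subtype)
  )
  jsonlite::write_json(report, out("survival_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  manifest <- list(
    package = "vascreen",
    version = as.character(utils::packageVersion("vascreen")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    n_genes_scored = nrow(screen$scores),
    n_genes_dropped = nrow(screen$dropped),
    n_enriched = sum(screen$scores$enriched),
    n_ce_high_associated = sum(diff_tab$ce_class == "CE-high-associated"),
    n_ce_low_associated = sum(diff_tab$ce_class == "CE-low-associated"),
    n_samples = length(shared),
    outputs = c("enrichment.tsv", "histogram.tsv", "diff_scores.tsv",
                sprintf("km_%s.tsv", names(comparison$km)),
                "survival_report.json", "manifest.json")
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  invisible(list(screen = screen, histogram = hist_tab, features = features,
                 extremes = extremes, diff_scores = diff_tab,
                 comparison = comparison, cox = cox, subgroups = subgroups,
                 subtype = subtype, report = report, manifest = manifest,
                 out_dir = config$out_dir))
}
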