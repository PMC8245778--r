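# Survival stratification by the enhancing-volume fraction: median split,
# Kaplan-Meier product-limit curves, log-rank comparison, Cox model with age
# adjustment, age subgroups, and the EV/CV-by-subtype comparison. KM and
# log-rank are implemented from their definitions (and cross-checked against
# the survival package in the test suite); the Cox fit is delegated to
# survival::coxph with the Efron tie correction.

#' Median split of the cohort by EV/CV ratio
#'
#' Samples with ratio above the median become CE-high, at or below the median
#' CE-low (median ties are assigned to CE-low — an arbitrary but deterministic
#' convention). With even n and no ties the groups are equal-sized.
#'
#' @param features A [compute_segmentation_features()] table.
#' @return data.frame of class `"group_assignment"` (`sample_id`, `ratio`,
#'   `group`), attribute `cutoff` = the median.
#' @export
median_split <- function(features) {
  if (!all(c("sample_id", "ratio") %in% names(features))) {
    abort_data("median_split: need sample_id and ratio columns")
  }
  keep <- is.finite(features$ratio)
  features <- features[keep, , drop = FALSE]
  if (nrow(features) < 2L) abort_data("median_split: need at least 2 samples")
  med <- stats::median(features$ratio)
  if (all(features$ratio == features$ratio[1L])) {
    abort_data("median_split: all ratios identical, no split possible")
  }
  out <- data.frame(sample_id = as.character(features$sample_id),
                    ratio = features$ratio,
                    group = ifelse(features$ratio > med, "CE-high", "CE-low"),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", "data.frame")
  attr(out, "cutoff") <- med
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct
#' event times \eqn{t_i}. A censored-only sample gives \eqn{\hat S \equiv 1}.
#' The median survival is the smallest time with \eqn{\hat S \le 0.5}
#' (`NA` when the curve never reaches 0.5).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return List of class `"km_fit"`: `table` (data.frame `time`, `n_risk`,
#'   `n_event`, `survival` at distinct event times), `median`, `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L || length(times) != length(events)) {
    abort_data("km_estimate: need equal-length non-empty times and events")
  }
  if (any(!is.finite(times) | times <= 0)) abort_data("km_estimate: times must be positive")
  if (!all(events %in% c(0, 1))) abort_data("km_estimate: events must be 0/1")
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) ev_times[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(table = data.frame(time = ev_times, n_risk = n_risk,
                                    n_event = n_event, survival = surv),
                 median = med, n = length(times)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("km_fit: n = %d, %d event times, median = %s\n",
              x$n, nrow(x$table), format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct pooled event time, the observed events in group A are
#' compared with the hypergeometric expectation given the risk sets;
#' \eqn{\chi^2 = (\sum O - \sum E)^2 / \sum V} on 1 df. With no events
#' anywhere the statistic is undefined and reported as missing.
#'
#' @param times_a,events_a Group A follow-up times and 0/1 events.
#' @param times_b,events_b Group B.
#' @return List of class `"logrank_result"`: `chi2`, `p`, `observed`,
#'   `expected` (group A totals), `n_a`, `n_b`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) abort_data("logrank_test: both groups need subjects")
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  in_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  if (any(!is.finite(time) | time <= 0)) abort_data("logrank_test: times must be positive")
  if (!all(event %in% c(0, 1))) abort_data("logrank_test: events must be 0/1")
  ev_times <- sort(unique(time[event == 1]))
  if (!length(ev_times)) {
    return(structure(list(chi2 = NA_real_, p = NA_real_, observed = 0,
                          expected = NA_real_, n_a = length(times_a),
                          n_b = length(times_b)),
                     class = "logrank_result"))
  }
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_a)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else NA_real_
  p <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(chi2 = chi2, p = p, observed = O, expected = E,
                 n_a = length(times_a), n_b = length(times_b)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.4f, p = %.4g (n = %d vs %d)\n",
              x$chi2, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Cox proportional hazards fit (Efron ties)
#'
#' Thin contract over `survival::coxph(ties = "efron")`: per covariate the
#' hazard ratio, Wald 95% CI and p-value, plus the score test at beta = 0
#' (which equals the log-rank chi-square for a single binary covariate with
#' no tied event times). Constant covariates and non-converged or separated
#' fits are rejected with a diagnostic.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param covariates data.frame (or matrix) of numeric covariates; factors
#'   must be pre-coded.
#' @return List of class `"cox_fit"`: `table` (data.frame `term`, `coef`,
#'   `se`, `hr`, `ci_lo`, `ci_hi`, `p`), `score_chi2`, `loglik`, `n`,
#'   `n_event`.
#' @export
cox_fit <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  if (!nrow(covariates) || nrow(covariates) != length(times)) {
    abort_data("cox_fit: covariates must have one row per subject")
  }
  if (any(!is.finite(times) | times <= 0)) abort_data("cox_fit: times must be positive")
  if (!all(events %in% c(0, 1))) abort_data("cox_fit: events must be 0/1")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) abort_data("cox_fit: covariate '%s' must be numeric", nm)
    if (length(unique(v[is.finite(v)])) < 2L) {
      abort_data("cox_fit: covariate '%s' is constant (no information)", nm)
    }
  }
  if (sum(events) < ncol(covariates)) {
    abort_data("cox_fit: fewer events (%d) than covariates (%d)", sum(events), ncol(covariates))
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w))) {
        abort_data("cox_fit: fit failed (%s)", conditionMessage(w))
      }
      suppressWarnings(survival::coxph(fml, data = dat, ties = "efron",
                                       control = survival::coxph.control(eps = 1e-9, iter.max = 100)))
    },
    error = function(e) abort_data("cox_fit: %s", conditionMessage(e))
  )
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15)) {
    abort_data("cox_fit: monotone likelihood / perfect separation detected")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(0.975)
  tab <- data.frame(term = names(covariates), coef = unname(beta), se = unname(se),
                    hr = exp(unname(beta)),
                    ci_lo = exp(unname(beta) - zq * se),
                    ci_hi = exp(unname(beta) + zq * se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, score_chi2 = unname(fit$score),
                 loglik = fit$loglik, n = fit$n, n_event = fit$nevent),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d\n", x$n, x$n_event))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# join features + clinical on sample_id (order-independent), run the median
# split and the two-group survival comparison
survival_comparison <- function(features, clinical, use_global_median = FALSE,
                                global_cutoff = NULL) {
  dat <- merge(features[, c("sample_id", "ratio")],
               clinical[, c("sample_id", "os_time", "os_event")],
               by = "sample_id")
  dat <- dat[is.finite(dat$os_time) & !is.na(dat$os_event), , drop = FALSE]
  if (nrow(dat) < 4L) return(list(evaluable = FALSE, reason = "fewer than 4 usable samples"))
  split <- if (use_global_median && !is.null(global_cutoff)) {
    out <- data.frame(sample_id = dat$sample_id, ratio = dat$ratio,
                      group = ifelse(dat$ratio > global_cutoff, "CE-high", "CE-low"),
                      stringsAsFactors = FALSE)
    class(out) <- c("group_assignment", "data.frame"); attr(out, "cutoff") <- global_cutoff
    out
  } else {
    median_split(dat)
  }
  dat$group <- split$group[match(dat$sample_id, split$sample_id)]
  hi <- dat[dat$group == "CE-high", ]
  lo <- dat[dat$group == "CE-low", ]
  if (nrow(hi) < 2L || nrow(lo) < 2L) return(list(evaluable = FALSE, reason = "a split side has < 2 samples"))
  list(evaluable = TRUE,
       cutoff = attr(split, "cutoff"),
       km = list("CE-high" = km_estimate(hi$os_time, hi$os_event),
                 "CE-low" = km_estimate(lo$os_time, lo$os_event)),
       logrank = logrank_test(hi$os_time, hi$os_event, lo$os_time, lo$os_event),
       n = c("CE-high" = nrow(hi), "CE-low" = nrow(lo)))
}

#' Survival comparison within age subgroups
#'
#' Re-runs the median split, Kaplan-Meier estimation and log-rank test
#' separately in patients younger than `cutoff` years and in those at least
#' `cutoff`. By default the EV/CV median is recomputed within each age
#' stratum; set `use_global_median = TRUE` to reuse the whole-cohort cutoff.
#' An empty (or too small) stratum is reported as not evaluable rather than
#' raising an error.
#'
#' @param features Segmentation features table.
#' @param clinical Clinical table with `age`.
#' @param cutoff Age cutoff in years (default 60).
#' @param use_global_median Reuse the pooled median EV/CV cutoff (default
#'   FALSE).
#' @return List with `younger` and `older` comparisons (each as from the
#'   pooled analysis, or `evaluable = FALSE` with a reason) and `cutoff`.
#' @export
age_subgroup_analysis <- function(features, clinical, cutoff = 60,
                                  use_global_median = FALSE) {
  stopifnot_scalar_number(cutoff, "cutoff", 0, 150)
  if (!"age" %in% names(clinical)) abort_data("age_subgroup_analysis: clinical table lacks 'age'")
  global_cutoff <- stats::median(features$ratio[is.finite(features$ratio)])
  run_stratum <- function(keep_ids) {
    cl <- clinical[clinical$sample_id %in% keep_ids, , drop = FALSE]
    fe <- features[features$sample_id %in% keep_ids, , drop = FALSE]
    if (nrow(cl) < 4L) return(list(evaluable = FALSE, reason = "stratum too small"))
    tryCatch(survival_comparison(fe, cl, use_global_median, global_cutoff),
             vascreen_data_error = function(e) list(evaluable = FALSE, reason = conditionMessage(e)))
  }
  young_ids <- clinical$sample_id[!is.na(clinical$age) & clinical$age < cutoff]
  old_ids <- clinical$sample_id[!is.na(clinical$age) & clinical$age >= cutoff]
  list(younger = run_stratum(young_ids), older = run_stratum(old_ids),
       cutoff = cutoff)
}

#' Compare EV/CV ratio between mesenchymal and non-mesenchymal tumors
#'
#' Two-sided pooled-variance Student's t-test of the EV/CV ratio, mesenchymal
#' vs all other subtypes pooled ("unknown" excluded). When the pooled SD is
#' exactly zero the t statistic is undefined: equal means report t = 0 /
#' p = 1, unequal means are flagged as infinite separation (`t = NA`,
#' `p = NA`, `separated = TRUE`) — no epsilon fudging.
#'
#' @param features Segmentation features table.
#' @param clinical Clinical table with `subtype`.
#' @return List of class `"subtype_comparison"`: `t`, `df`, `p`, `separated`,
#'   `mean_mes`, `mean_other`, `n_mes`, `n_other`.
#' @export
compare_ratio_by_subtype <- function(features, clinical) {
  if (!"subtype" %in% names(clinical)) abort_data("compare_ratio_by_subtype: clinical table lacks 'subtype'")
  dat <- merge(features[, c("sample_id", "ratio")],
               clinical[, c("sample_id", "subtype")], by = "sample_id")
  dat <- dat[is.finite(dat$ratio) & !is.na(dat$subtype) & dat$subtype != "unknown", ]
  x <- dat$ratio[dat$subtype == "mesenchymal"]
  y <- dat$ratio[dat$subtype != "mesenchymal"]
  if (length(x) < 2L || length(y) < 2L) {
    abort_data("compare_ratio_by_subtype: need >= 2 samples per pool (got %d mesenchymal, %d other)",
               length(x), length(y))
  }
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  res <- list(df = df, separated = FALSE,
              mean_mes = mean(x), mean_other = mean(y),
              n_mes = n1, n_other = n2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) { res$t <- 0; res$p <- 1 }
    else { res$t <- NA_real_; res$p <- NA_real_; res$separated <- TRUE }
  } else {
    res$t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    res$p <- 2 * stats::pt(-abs(res$t), df = df)
  }
  structure(res, class = "subtype_comparison")
}

#' @export
print.subtype_comparison <- function(x, ...) {
  cat(sprintf("EV/CV mesenchymal (n=%d, mean %.3f) vs other (n=%d, mean %.3f): t = %s, p = %s%s\n",
              x$n_mes, x$mean_mes, x$n_other, x$mean_other,
              format(x$t), format(x$p),
              if (x$separated) " [infinite separation]" else ""))
  invisible(x)
}
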