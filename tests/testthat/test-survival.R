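# survival stack: median split, KM, log-rank, Cox, subgroups, subtype t-test

feats_from_ratio <- function(r, ids = sprintf("P%02d", seq_along(r))) {
  structure(data.frame(sample_id = ids, EV = r, NV = 1 - r, CV = 1, ratio = r,
                       stringsAsFactors = FALSE),
            class = c("segmentation_features", "data.frame"))
}

test_that("median split follows the documented tie convention", {
  g <- median_split(feats_from_ratio(c(0.1, 0.2, 0.8, 0.9)))
  expect_identical(g$group, c("CE-low", "CE-low", "CE-high", "CE-high"))

  g3 <- median_split(feats_from_ratio(c(0.1, 0.5, 0.9)))
  expect_identical(g3$group[2], "CE-low")     # exactly at the median -> CE-low

  expect_error(median_split(feats_from_ratio(rep(0.4, 6))), class = "vascreen_data_error")

  set.seed(8)
  for (i in 1:30) {
    r <- sample(round(runif(12), 1), 12, replace = TRUE)
    if (length(unique(r)) < 2) next
    g <- median_split(feats_from_ratio(r))
    med <- median(r)
    # brute-force comparison oracle
    expect_identical(g$group, ifelse(r > med, "CE-high", "CE-low"))
    # ties all go CE-low, so each median-tied sample can shift the balance
    # by two relative to a tie-free split
    n_tied <- sum(r == med)
    expect_lte(abs(sum(g$group == "CE-high") - sum(g$group == "CE-low")),
               max(2L * n_tied, 1L))
  }
})

test_that("KM estimator matches hand product-limit results and survfit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival, c(2/3, 1/3, 0))
  expect_equal(km$median, 2)

  cens <- km_estimate(c(5, 9, 13), c(0, 0, 0))
  expect_equal(nrow(cens$table), 0)           # S(t) = 1 throughout
  expect_true(is.na(cens$median))

  # worked 4-subject example: 1, 2+, 3, 4
  km4 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km4$table$time, c(1, 3, 4))
  expect_equal(km4$table$survival, c(3/4, 3/8, 0))

  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    tm <- round(rexp(n, 0.1), 1) + 0.1
    ev <- rbinom(n, 1, 0.7)
    if (!sum(ev)) next
    km <- km_estimate(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    keep <- sf$n.event > 0
    expect_equal(km$table$time, sf$time[keep])
    expect_equal(km$table$survival, sf$surv[keep], tolerance = 1e-12)
    # no censoring beyond the last event: KM there equals the empirical fraction
    if (all(ev == 1)) expect_equal(min(km$table$survival), 0)
  }
  expect_error(km_estimate(c(0, 1), c(1, 1)), class = "vascreen_data_error")
})

test_that("log-rank matches the brute-force oracle, survdiff, and is symmetric", {
  t1 <- c(3, 6, 9); e1 <- c(1, 0, 1)
  t2 <- c(2, 5, 11); e2 <- c(1, 1, 0)
  res <- logrank_test(t1, e1, t2, e2)
  orc <- oracle_logrank(t1, e1, t2, e2)
  expect_equal(res$chi2, orc$chi2, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)

  sd <- survival::survdiff(survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, each = 3))
  expect_equal(res$chi2, sd$chisq, tolerance = 1e-9)

  # exchangeable groups -> chi2 = 0, p = 1
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(4:20, 1); n2 <- sample(4:20, 1)
    ta <- round(rexp(n1, 0.2), 2) + 0.01; ea <- rbinom(n1, 1, 0.8)
    tb <- round(rexp(n2, 0.3), 2) + 0.01; eb <- rbinom(n2, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    a <- logrank_test(ta, ea, tb, eb)
    b <- logrank_test(tb, eb, ta, ea)
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    expect_equal(a$chi2, oracle_logrank(ta, ea, tb, eb)$chi2, tolerance = 1e-12)
  }

  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(is.na(none$chi2))   # no events anywhere -> undefined
})

test_that("Cox fit recovers effects, rejects degenerate designs, equals log-rank score", {
  expect_error(cox_fit(c(1, 2, 3, 4), c(1, 1, 1, 1),
                       data.frame(x = rep(2, 4))),
               "constant", class = "vascreen_data_error")

  # score test at beta = 0 equals the log-rank chi2 on tie-free data
  set.seed(11)
  tm <- sort(rexp(30, 0.1)) + (1:30) * 1e-4   # guarantee no ties
  grp <- rbinom(30, 1, 0.5)
  ev <- rbinom(30, 1, 0.85)
  fit <- cox_fit(tm, ev, data.frame(group = grp))
  lr <- logrank_test(tm[grp == 1], ev[grp == 1], tm[grp == 0], ev[grp == 0])
  expect_equal(fit$score_chi2, lr$chi2, tolerance = 1e-9)

  # parameter recovery at a moderate size (the n = 500 run lives in acceptance)
  set.seed(12)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.01 * exp(log(2) * x))
  cc <- rexp(n, rate = 0.004)
  fit2 <- cox_fit(pmin(tt, cc), as.numeric(tt <= cc), data.frame(x = x))
  expect_gt(fit2$table$hr, 1.4)
  expect_lt(fit2$table$hr, 2.9)
  expect_true(fit2$table$ci_lo < 2 && 2 < fit2$table$ci_hi)

  # sign of the coefficient matches the KM median ordering
  km1 <- km_estimate(pmin(tt, cc)[x == 1], as.numeric(tt <= cc)[x == 1])
  km0 <- km_estimate(pmin(tt, cc)[x == 0], as.numeric(tt <= cc)[x == 0])
  expect_true((fit2$table$coef > 0) == (km1$median < km0$median))

  # perfect separation is flagged, not silently reported
  expect_error(
    cox_fit(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1),
            data.frame(x = c(1, 1, 1, 0, 0, 0))),
    class = "vascreen_data_error"
  )
})

test_that("age subgroup analysis recomputes medians per stratum and degrades gracefully", {
  ds <- generate_dataset(mixture_config(seed = 4, n_genes = 10, n_ec_constitutive = 2,
                                        n_ce_high_conditional = 2, n_ce_low_conditional = 2))
  feats <- compute_segmentation_features(ds$segmentation)
  res <- age_subgroup_analysis(feats, ds$clinical, cutoff = 60)
  expect_true(res$younger$evaluable)
  expect_true(res$older$evaluable)
  young <- ds$clinical$age < 60
  expect_equal(res$younger$cutoff,
               median(feats$ratio[feats$sample_id %in% ds$clinical$sample_id[young]]))

  # all patients young -> older stratum not evaluable, no exception
  cl_young <- ds$clinical; cl_young$age <- 40
  res2 <- age_subgroup_analysis(feats, cl_young)
  expect_false(res2$older$evaluable)
  expect_true(res2$younger$evaluable)
  # identical data in both strata -> identical statistics
  expect_equal(res2$younger$logrank$chi2,
               vascreen:::survival_comparison(feats, ds$clinical)$logrank$chi2)
})

test_that("subtype comparison equals the pooled-variance formula with exact degeneracy rules", {
  mk <- function(r, st) {
    list(f = feats_from_ratio(r), cl = data.frame(sample_id = sprintf("P%02d", seq_along(r)),
                                                  os_time = 1, os_event = 1, age = 50,
                                                  subtype = st, stringsAsFactors = FALSE))
  }
  same <- mk(rep(c(0.4, 0.6), 4), rep(c("mesenchymal", "proneural"), 4))
  # identical pools -> t = 0, p = 1
  eq <- mk(c(0.3, 0.5, 0.3, 0.5), c("mesenchymal", "mesenchymal", "classical", "neural"))
  res_eq <- compare_ratio_by_subtype(eq$f, eq$cl)
  expect_equal(res_eq$t, 0)
  expect_equal(res_eq$p, 1)

  sep <- mk(c(0, 0, 0, 1, 1, 1), rep(c("mesenchymal", "neural"), each = 3))
  res_sep <- compare_ratio_by_subtype(sep$f, sep$cl)
  expect_true(res_sep$separated)
  expect_true(is.na(res_sep$t))

  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    r <- c(runif(n1), runif(n2))
    st <- rep(c("mesenchymal", "proneural"), c(n1, n2))
    d <- mk(r, st)
    res <- compare_ratio_by_subtype(d$f, d$cl)
    orc <- oracle_t(r[1:n1], r[-(1:n1)])
    expect_equal(res$t, orc$t, tolerance = 1e-12)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
    expect_equal(res$p, t.test(r[1:n1], r[-(1:n1)], var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(compare_ratio_by_subtype(same$f[1:2, ],
                                        same$cl[same$cl$sample_id %in% same$f$sample_id[1:2], ]),
               class = "vascreen_data_error")
})

test_that("null-simulation Cox CIs cover beta = 0 at the nominal rate", {
  set.seed(14)
  reps <- 2000
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.01)
    cc <- rexp(n, 0.0035)
    fit <- tryCatch(cox_fit(pmin(tt, cc), as.numeric(tt <= cc), data.frame(x = x)),
                    vascreen_data_error = function(e) NULL)
    covered[i] <- !is.null(fit) && fit$table$ci_lo < 1 && 1 < fit$table$ci_hi
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.97)
})
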