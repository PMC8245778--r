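# imaging phenotype, extremes dichotomization, differential correlation

test_that("segmentation features follow CV = EV + NV and reject bad volumes", {
  vols <- data.frame(sample_id = c("a", "b", "c"),
                     EV = c(30, 0, 50), NV = c(70, 50, 0))
  f <- compute_segmentation_features(vols)
  expect_equal(f$CV, c(100, 50, 50))
  expect_equal(f$ratio, c(0.3, 0, 1))

  expect_error(compute_segmentation_features(
    data.frame(sample_id = "x", EV = -1, NV = 5)), "x", class = "vascreen_data_error")
  expect_error(compute_segmentation_features(
    data.frame(sample_id = "zed", EV = 0, NV = 0)), "zed", class = "vascreen_data_error")
})

test_that("dichotomization takes exact extremes with deterministic tie-breaks", {
  set.seed(7)
  feats <- compute_segmentation_features(
    data.frame(sample_id = sprintf("S%03d", 1:128),
               EV = runif(128, 1, 100), NV = runif(128, 1, 100)))
  g <- dichotomize_extremes(feats, k = 20)
  expect_equal(sum(g$group == "CE-high"), 20)
  expect_equal(sum(g$group == "CE-low"), 20)
  expect_equal(sum(g$group == "unassigned"), 88)
  expect_length(intersect(g$sample_id[g$group == "CE-high"],
                          g$sample_id[g$group == "CE-low"]), 0)

  expect_error(dichotomize_extremes(feats[1:5, ], k = 3), "n = 5",
               class = "vascreen_config_error")

  # boundary ties resolved by ascending sample id; interior ties irrelevant
  tied <- compute_segmentation_features(
    data.frame(sample_id = c("d", "c", "b", "a"),
               EV = c(1, 2, 2, 9), NV = c(9, 8, 8, 1)))
  g1 <- dichotomize_extremes(tied, k = 1)
  expect_equal(g1$sample_id[g1$group == "CE-high"], "a")
  expect_equal(g1$sample_id[g1$group == "CE-low"], "d")
  g2 <- dichotomize_extremes(tied, k = 2)
  # brute-force stable-sort oracle: CE-low by (ratio, id); CE-high by
  # (-ratio, id) among the samples CE-low did not claim
  df <- data.frame(id = tied$sample_id, r = tied$ratio)
  lo_oracle <- df$id[order(df$r, df$id)][1:2]
  hi_oracle <- setdiff(df$id[order(-df$r, df$id)], lo_oracle)[1:2]
  expect_setequal(g2$sample_id[g2$group == "CE-low"], lo_oracle)
  expect_setequal(g2$sample_id[g2$group == "CE-high"], hi_oracle)
})

test_that("identical groups give zero scores and label swaps negate them", {
  ds <- generate_dataset(tiny_config())
  ids <- colnames(ds$expression)
  genes <- c("ECG0001", "ECG0002", "CEH0001", "BG00001")

  same <- differential_correlation_score(ds$expression, marker_panel(), genes,
                                         list(high = ids[1:10], low = ids[1:10]))
  expect_equal(same$delta, rep(0, length(genes)))

  fwd <- differential_correlation_score(ds$expression, marker_panel(), genes,
                                        make_groups(ids, ids[1:10], ids[11:20]))
  rev <- differential_correlation_score(ds$expression, marker_panel(), genes,
                                        make_groups(ids, ids[11:20], ids[1:10]))
  expect_equal(fwd$delta, -rev$delta)
  expect_identical(fwd$corr_high, rev$corr_low)
  expect_equal(fwd$delta, fwd$corr_high - fwd$corr_low, tolerance = 1e-12)
  expect_true(all(abs(fwd$delta) <= 2))

  expect_error(
    differential_correlation_score(ds$expression, marker_panel(), genes,
                                   make_groups(ids, ids[1:2], ids[3:12])),
    class = "vascreen_data_error"
  )
})

test_that("genes constant within a group are reported unclassifiable", {
  ds <- generate_dataset(tiny_config(noise_sd = 0))
  ids <- colnames(ds$expression)
  z <- ds$truth$samples$ce_latent
  lo_ids <- ids[order(z)][1:8]     # bottom of the latent scale: CEH genes flat
  hi_ids <- ids[order(-z)][1:8]
  tab <- differential_correlation_score(ds$expression, marker_panel(),
                                        c("CEH0001", "ECG0001"),
                                        list(high = hi_ids, low = lo_ids))
  ceh <- tab[tab$gene_id == "CEH0001", ]
  expect_true(is.na(ceh$corr_low))
  expect_identical(ceh$ce_class, "unclassifiable")
  expect_match(ceh$reason, "zero variance")
  expect_false(is.na(tab$delta[tab$gene_id == "ECG0001"]))
})

test_that("classification is strict, idempotent and validated", {
  tab <- structure(
    data.frame(gene_id = c("a", "b", "c", "d"),
               corr_high = c(0.5, 0.4, 0.1, 0.2),
               corr_low = c(0.35, 0.3, 0.51, 0.2),
               delta = c(0.15, 0.1, -0.41, 0),
               stringsAsFactors = FALSE),
    class = c("differential_score_table", "data.frame")
  )
  out <- classify_ce_association(tab)
  expect_identical(out$ce_class,
                   c("CE-high-associated", "unclassified", "CE-low-associated", "unclassified"))
  expect_identical(classify_ce_association(out)$ce_class, out$ce_class)  # idempotent
  expect_error(classify_ce_association(tab, up_threshold = -0.5, down_threshold = 0.1),
               class = "vascreen_config_error")
})

test_that("ec_rank in the score table matches the full-cohort screen exactly", {
  ds <- generate_dataset(tiny_config())
  scr <- enrichment_screen(marker_correlation_profile(ds$expression))
  feats <- compute_segmentation_features(ds$segmentation)
  grp <- dichotomize_extremes(feats, k = 8)
  tab <- differential_correlation_score(ds$expression, marker_panel(), scr, grp)
  expect_setequal(tab$gene_id, enriched_genes(scr))
  sc <- scr$scores
  expect_identical(tab$ec_rank, sc$rank[match(tab$gene_id, sc$gene_id)])
  expect_true(all(tab$n_high == 8) && all(tab$n_low == 8))
})
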