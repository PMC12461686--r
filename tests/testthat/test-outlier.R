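# small trained pipeline shared by this file
out_x <- two_cluster_matrix(n = 200, p = 30, seed = 35)
out_e <- normalize_embedding(embed_reference(out_x, "tsne", dims = 2,
                                             perplexity = 15, seed = 36))
out_cfg <- train_config(seed = 37, max_epochs = 300)
out_fwd <- fit_forward(out_x, out_e, out_cfg)
out_inv <- fit_inverse(out_e, out_x, out_cfg)

test_that("k = 1 novelty distances equal a brute-force nearest-neighbour scan", {
  xm <- unclass(out_x)[1:100, ]
  sc <- novelty_score(out_fwd, xm, out_e, k = 1)
  proj <- predict(out_fwd, xm)
  ref <- out_e$coords
  brute <- vapply(seq_len(nrow(proj)), function(i)
    min(sqrt(rowSums(sweep(ref, 2, proj[i, ])^2))), numeric(1))
  expect_equal(sc$knn_dist, brute, tolerance = 1e-10)
})

test_that("a sample identical to a training sample scores as in-distribution", {
  xm <- unclass(out_x)[5, , drop = FALSE]
  sc <- novelty_score(out_fwd, xm, out_e, k = 10)
  thr <- calibrate_threshold(training_self_scores(out_e, k = 10), 0.99)
  expect_lt(sc$knn_dist, thr)
  expect_error(novelty_score(out_fwd, xm, out_e, k = 10000), "training size")
})

test_that("scores are row-order invariant and include the round-trip score when asked", {
  xm <- unclass(out_x)[11:20, ]
  sc1 <- novelty_score(out_fwd, xm, out_e, k = 5, inv = out_inv)
  sc2 <- novelty_score(out_fwd, xm[10:1, ], out_e, k = 5, inv = out_inv)
  expect_equal(sc1$knn_dist, rev(sc2$knn_dist), tolerance = 1e-12)
  expect_true(all(c("knn_dist", "roundtrip") %in% names(sc1)))
  expect_true(all(sc1$roundtrip >= 0))
})

test_that("calibrate_threshold is the empirical quantile, checked against a sort oracle", {
  expect_equal(calibrate_threshold(rep(3.5, 25), 0.9), 3.5)

  sc <- as.numeric(1:100)
  got <- calibrate_threshold(sc, 0.99)
  expect_equal(got, unname(quantile(sc, 0.99, type = 7)))
  # sort-based check of the type-7 definition: interpolation at h = 1 + 99 p
  h <- 1 + 99 * 0.99
  srt <- sort(sc)
  expect_equal(got, srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)]))

  sym <- c(1:10, 20 - (1:10))
  expect_equal(calibrate_threshold(sym, 0.5), median(sym))
  expect_error(calibrate_threshold(1:5, 0.5), "at least 20")
  expect_error(calibrate_threshold(1:30, 1.2), "\\(0, 1\\)")
})

test_that("novelty flags are consistent with the threshold and monotone in the quantile", {
  withr::with_seed(39, {
    scores <- rexp(200)
    q_seq <- c(0.5, 0.8, 0.9, 0.99)
    flags <- vapply(q_seq, function(q) {
      rep_ <- novelty_report(scores, calibrate_threshold(scores, q))
      expect_identical(rep_$flag, rep_$score > attr(rep_, "threshold"))
      sum(rep_$flag)
    }, numeric(1))
    expect_true(all(diff(flags) <= 0))  # raising the quantile never adds flags
  })
})

test_that("planted novel clusters are separated from replicates (AUROC) and null offsets are not", {
  so <- synth_outliers(n_train = 400, n_new = 80, n_features = 120,
                       offset = 5, seed = 40)
  e <- normalize_embedding(embed_reference(so$train, "tsne", dims = 2,
                                           perplexity = 20, seed = 41))
  fwd <- fit_forward(so$train, e, train_config(seed = 42, max_epochs = 300))
  sc <- novelty_score(fwd, rbind(unclass(so$replicate), unclass(so$novel)), e, k = 10)
  expect_gte(auroc(sc$knn_dist, so$truth), 0.9)

  so0 <- synth_outliers(n_train = 400, n_new = 80, n_features = 120,
                        offset = 0, seed = 43)
  e0 <- normalize_embedding(embed_reference(so0$train, "tsne", dims = 2,
                                            perplexity = 20, seed = 44))
  fwd0 <- fit_forward(so0$train, e0, train_config(seed = 45, max_epochs = 300))
  sc0 <- novelty_score(fwd0, rbind(unclass(so0$replicate), unclass(so0$novel)), e0, k = 10)
  expect_lt(abs(auroc(sc0$knn_dist, so0$truth) - 0.5), 0.15)
})
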