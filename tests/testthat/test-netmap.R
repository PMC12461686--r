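# deterministic split behaviour ---------------------------------------------

test_that("split_data produces disjoint exhaustive sets at the 70/15/15 fractions", {
  s <- split_data(100, train_config(seed = 1))
  expect_length(s$train, 70)
  expect_length(s$test, 15)
  expect_length(s$val, 15)

  s2 <- split_data(101, train_config(seed = 2))
  expect_equal(length(s2$train) + length(s2$test) + length(s2$val), 101)
  expect_true(abs(length(s2$train) - 70.7) <= 1)
  expect_true(abs(length(s2$test) - 15.15) <= 1)
  expect_setequal(c(s2$train, s2$test, s2$val), 1:101)

  expect_identical(split_data(57, train_config(seed = 3)),
                   split_data(57, train_config(seed = 3)))
  expect_error(split_data(5, train_config()), "at least 10")
})

# forward map ----------------------------------------------------------------

test_that("forward training recovers an exactly realizable linear target", {
  withr::with_seed(71, {
    x <- matrix(runif(200 * 8), 200, 8)
    w <- matrix(rnorm(8 * 3), 8, 3)
    y <- x %*% w
    y <- sweep(y, 2, apply(y, 2, min))
    y <- sweep(y, 2, apply(y, 2, max), "/")
    e <- embedding(y, method = "network", normalized = TRUE)
    fwd <- fit_forward(x, e, train_config(seed = 4, max_epochs = 1000,
                                          learning_rate = 3e-3))
    expect_gte(min(fwd$diagnostics$r2_test), 0.999)
  })
})

test_that("shuffled targets give near-zero held-out r2 (negative control)", {
  x <- two_cluster_matrix(n = 200, p = 30, seed = 14)
  e <- normalize_embedding(embed_reference(x, "tsne", dims = 2, perplexity = 15, seed = 3))
  ep <- withr::with_seed(99, embedding(e$coords[sample.int(200), ],
                                       method = "network", normalized = TRUE))
  expect_warning(
    fwd <- fit_forward(x, ep, train_config(seed = 4, max_epochs = 150, patience = 20)),
    "baseline")
  expect_lt(max(fwd$diagnostics$r2_test), 0.2)
})

test_that("inverse training fits a coordinate-valued feature exactly and beats the mean baseline", {
  withr::with_seed(73, {
    co <- matrix(runif(300 * 2), 300, 2)
    e <- embedding(co, method = "network", normalized = TRUE)
    target <- matrix(co[, 1], ncol = 1)  # one feature equal to a coordinate
    inv <- fit_inverse(e, target, train_config(seed = 5))
    expect_gte(min(inv$diagnostics$r2_test), 0.999)
  })

  # round trip beats the dataset-mean spectrum on training samples
  x <- two_cluster_matrix(n = 200, p = 30, seed = 15)
  e <- normalize_embedding(embed_reference(x, "tsne", dims = 2, perplexity = 15, seed = 6))
  cfg <- train_config(seed = 7, max_epochs = 400)
  fwd <- fit_forward(x, e, cfg)
  inv <- fit_inverse(e, x, cfg)
  xm <- unclass(x)
  recon <- predict(inv, predict(fwd, xm))
  mse_round <- mean((recon - xm)^2)
  mse_mean <- mean(sweep(xm, 2, colMeans(xm))^2)
  expect_lt(mse_round, mse_mean)
})

# apply_map contract ----------------------------------------------------------

test_that("predict is deterministic, chunk-independent and dimension-checked", {
  x <- two_cluster_matrix(n = 150, p = 12, seed = 16)
  e <- normalize_embedding(embed_reference(x, "tsne", dims = 2, perplexity = 12, seed = 8))
  fwd <- fit_forward(x, e, train_config(seed = 9, max_epochs = 200))
  xm <- unclass(x)

  whole <- predict(fwd, xm)
  tiny <- predict(fwd, xm, chunk_size = 1L)
  mid <- predict(fwd, xm, chunk_size = 64L)
  # identical up to the last-ulp rounding of the BLAS kernels selected for
  # different chunk shapes; repeated calls at one chunk size are bitwise equal
  expect_equal(whole, tiny, tolerance = 1e-12)
  expect_equal(whole, mid, tolerance = 1e-12)
  expect_identical(whole, predict(fwd, xm))

  # duplicate of a training row maps to exactly the same point
  dup <- xm[c(3, 3), , drop = FALSE]
  out <- predict(fwd, dup)
  expect_identical(out[1, ], out[2, ])

  expect_error(predict(fwd, xm[, 1:5]), "expects")
  bad <- xm; bad[1, 1] <- NA
  expect_error(predict(fwd, bad), "non-finite")
})

test_that("learned maps survive JSON serialization round-trips", {
  x <- two_cluster_matrix(n = 120, p = 10, seed = 17)
  e <- normalize_embedding(embed_reference(x, "tsne", dims = 2, perplexity = 10, seed = 10))
  fwd <- fit_forward(x, e, train_config(seed = 11, max_epochs = 150))
  path <- withr::local_tempfile(fileext = ".json")
  write_learned_map(fwd, path)
  back <- read_learned_map(path)
  expect_equal(predict(back, unclass(x)), predict(fwd, unclass(x)), tolerance = 1e-12)
  expect_equal(back$diagnostics$r2_test, unname(fwd$diagnostics$r2_test),
               tolerance = 1e-12)
  expect_identical(back$direction, "forward")
})

test_that("tidy and glance expose training diagnostics", {
  x <- two_cluster_matrix(n = 120, p = 10, seed = 18)
  e <- normalize_embedding(embed_reference(x, "tsne", dims = 2, perplexity = 10, seed = 12))
  fwd <- fit_forward(x, e, train_config(seed = 13, max_epochs = 100))
  td <- tidy(fwd)
  expect_named(td, c("dimension", "r2_train", "r2_val", "r2_test"))
  expect_equal(nrow(td), 2)
  expect_true(all(td$r2_test >= 0 & td$r2_test <= 1))
  gl <- glance(fwd)
  expect_equal(gl$direction, "forward")
  expect_equal(gl$min_r2_test, min(td$r2_test))
})
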