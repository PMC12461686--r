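# a tiny trained inverse map shared across this file
spec_x <- two_cluster_matrix(n = 150, p = 25, seed = 19)
spec_e <- normalize_embedding(embed_reference(spec_x, "tsne", dims = 2,
                                              perplexity = 12, seed = 14))
spec_inv <- fit_inverse(spec_e, spec_x, train_config(seed = 15, max_epochs = 400))

test_that("reverse_query returns deterministic pseudo-spectra and flags extrapolation", {
  a <- reverse_query(spec_inv, c(0.5, 0.5))
  b <- reverse_query(spec_inv, c(0.5, 0.5))
  expect_identical(a$contributions, b$contributions)
  expect_length(a$contributions, 25)
  expect_equal(a$feature_axis, feature_axis(spec_x))

  expect_warning(reverse_query(spec_inv, c(2, 0)), "extrapolat")
  expect_error(reverse_query(spec_inv, c(0.5, 0.5, 0.5)), "length")

  fwd_like <- spec_inv; fwd_like$direction <- "forward"
  expect_error(reverse_query(fwd_like, c(0.5, 0.5)), "inverse")
})

test_that("querying a training sample's position reconstructs its spectrum", {
  i <- 7L
  ps <- reverse_query(spec_inv, spec_e$coords[i, ])
  expect_gt(cor(ps$contributions, unclass(spec_x)[i, ]), 0.9)
})

test_that("centroid_spectrum averages coordinates before querying", {
  one <- centroid_spectrum(spec_inv, spec_e, 5L)
  direct <- reverse_query(spec_inv, spec_e$coords[5L, ])
  expect_equal(one$contributions, direct$contributions)

  mask <- rep(TRUE, nrow(spec_e$coords))
  allm <- centroid_spectrum(spec_inv, spec_e, mask)
  expect_equal(allm$query_point, unname(colMeans(spec_e$coords)))

  expect_error(centroid_spectrum(spec_inv, spec_e, rep(FALSE, 150)), "no samples")
})

test_that("rank_drivers orders by magnitude with sign filtering and mz tie-breaks", {
  ps <- structure(list(feature_axis = c(100, 200, 300),
                       contributions = c(0, 5, -7)),
                  class = "pseudo_spectrum")
  expect_equal(rank_drivers(ps, 1)$feature, 3L)
  expect_equal(rank_drivers(ps, 1, sign = "positive")$feature, 2L)
  expect_equal(rank_drivers(ps, 1, sign = "negative")$feature, 3L)

  tie <- structure(list(feature_axis = c(100, 50, 300),
                        contributions = c(2, -2, 1)),
                   class = "pseudo_spectrum")
  # |2| == |-2|: ascending m/z puts feature 2 (mz 50) first
  expect_equal(rank_drivers(tie, 2)$feature, c(2L, 1L))

  expect_warning(full <- rank_drivers(ps, 10), "clipping")
  expect_equal(sort(full$feature), 1:3)
})

test_that("rank_drivers agrees with a brute-force sort oracle and permutes all features", {
  withr::with_seed(91, {
    for (rep in 1:5) {
      p <- 30
      ps <- structure(list(feature_axis = sort(runif(p, 100, 900)),
                           contributions = rnorm(p)),
                      class = "pseudo_spectrum")
      got <- rank_drivers(ps, p)
      brute <- order(-abs(ps$contributions), ps$feature_axis)
      expect_equal(got$feature, brute)
      expect_setequal(got$feature, seq_len(p))
    }
  })
})

test_that("ppm_match applies the 5 ppm boundary arithmetic exactly", {
  tab <- annotation_table(c("PI(38:4)", "other"), c(885.5499, 900))
  hit <- ppm_match(885.550, tab)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$name, "PI(38:4)")
  expect_equal(abs(hit$ppm_error), abs(885.5499 - 885.550) / 885.550 * 1e6,
               tolerance = 1e-9)
  expect_lt(abs(hit$ppm_error), 5)

  exact <- ppm_match(885.5499, tab)
  expect_equal(exact$ppm_error[1], 0)

  beyond <- annotation_table("x", 885.550 * (1 + 6e-6))
  expect_equal(nrow(ppm_match(885.550, beyond, 5)), 0)
  expect_equal(nrow(ppm_match(885.550, beyond, 7)), 1)
})

test_that("ppm_match is monotone in the tolerance", {
  withr::with_seed(93, {
    tab <- annotation_table(paste0("m", 1:50), 500 * (1 + rnorm(50, 0, 1e-5)))
    tols <- c(1, 2, 5, 10, 20)
    sets <- lapply(tols, function(t) ppm_match(500, tab, t)$name)
    for (i in seq_len(length(tols) - 1))
      expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  })
})

test_that("annotation tables read from delimited text", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mass,adduct", "taurocholic acid,514.2839,[M-H]-",
               "PI(34:1),835.5342,[M-H]-"), path)
  tab <- read_annotation_table(path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mass[1], 514.2839)
  expect_error(annotation_table("x", -1), "positive")
})
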