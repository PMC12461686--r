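test_that("rgb_render maps coordinates to colour channels exactly", {
  co <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.2, 0.4, 0.6))
  e <- embedding(co, method = "network", normalized = TRUE)
  geom <- pixel_geometry(c(1, 2, 1, 2), c(1, 1, 2, 2))
  img <- rgb_render(e, geom)
  expect_equal(img[1, 1, ], c(1, 0, 0))  # pure red pixel
  expect_equal(img[1, 2, ], c(0, 1, 0))
  expect_equal(img[2, 1, ], c(0, 0, 1))
  # reading channels back recovers the coordinates exactly
  expect_equal(img[2, 2, ], c(0.2, 0.4, 0.6))
})

test_that("rgb_render keeps colour semantics across sections and blanks empty cells", {
  co <- rbind(c(0.3, 0.6, 0.9))
  e <- embedding(rbind(co, c(0, 0, 0)), method = "network", normalized = TRUE)
  g1 <- pixel_geometry(c(1, 2), c(1, 1), image_shape = c(3, 2))
  g2 <- pixel_geometry(c(2, 1), c(2, 2), image_shape = c(3, 2))
  i1 <- rgb_render(e, g1); i2 <- rgb_render(e, g2)
  expect_equal(i1[1, 1, ], i2[2, 2, ])      # same coords -> same colour
  expect_equal(i1[2, 3, ], c(0, 0, 0))      # unoccupied cell is black
  expect_error(rgb_render(e, pixel_geometry(1, 1)), "cover")
})

test_that("2-D embeddings render through the four-corner colour square", {
  co <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  e <- embedding(co, method = "network", normalized = TRUE)
  geom <- pixel_geometry(c(1, 2, 1, 2), c(1, 1, 2, 2))
  img <- rgb_render(e, geom)
  expect_equal(img[1, 1, ], c(0, 0, 1))  # blue corner
  expect_equal(img[1, 2, ], c(1, 0, 0))  # red corner
  expect_equal(img[2, 1, ], c(0, 1, 0))  # green corner
  expect_equal(img[2, 2, ], c(1, 1, 0))  # yellow corner
})

test_that("checkerboard regions render as a two-colour image matching the layout", {
  nx <- 6L; ny <- 6L
  px <- rep(1:nx, times = ny); py <- rep(1:ny, each = nx)
  region <- (px + py) %% 2L
  co <- cbind(ifelse(region == 0, 1, 0), 0, ifelse(region == 0, 0, 1))
  e <- embedding(co, method = "network", normalized = TRUE)
  img <- rgb_render(e, pixel_geometry(px, py))
  expect_equal(img[cbind(py, px, 1)], ifelse(region == 0, 1, 0))
  expect_equal(img[cbind(py, px, 3)], ifelse(region == 0, 0, 1))
})

test_that("box_mask is a closed containment test matching a brute-force scan", {
  withr::with_seed(101, {
    co <- matrix(runif(300), 100, 3)
    e <- embedding(co, method = "network", normalized = TRUE)
    expect_true(all(box_mask(e, c(0, 0, 0), c(1, 1, 1))))

    # degenerate box exactly at a point selects exactly that sample
    m <- box_mask(e, co[17, ], co[17, ])
    expect_equal(which(m), 17L)

    for (rep in 1:5) {
      lo <- runif(3, 0, 0.5); hi <- lo + runif(3, 0, 0.5)
      got <- box_mask(e, lo, hi)
      brute <- apply(co, 1, function(r) all(r >= lo & r <= hi))
      expect_identical(unname(got), brute)
    }
    expect_error(box_mask(e, c(0.5, 0, 0), c(0.2, 1, 1)), "lo")
  })
})

test_that("lda_loo is perfect on separable classes and chance-level on permuted labels", {
  withr::with_seed(103, {
    co <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
                matrix(rnorm(100, 5, 0.3), 50, 2))
    labs <- rep(c("a", "b"), each = 50)
    fit <- lda_loo(co, labs)
    expect_equal(fit$accuracy, 1.0)
    expect_equal(sum(fit$confusion), 100)

    perm <- sample(labs)
    acc_null <- lda_loo(co, perm)$accuracy
    # binomial 99% band around 0.5 for n = 100
    expect_true(acc_null > 0.5 - 2.58 * 0.05 - 0.05 &&
                acc_null < 0.5 + 2.58 * 0.05 + 0.05)
  })
})

test_that("lda_loo matches MASS::lda leave-one-out predictions on well-conditioned data", {
  withr::with_seed(107, {
    co <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
                matrix(rnorm(60, 1.5, 1), 30, 2))
    labs <- factor(rep(c("a", "b"), each = 30))
    ours <- lda_loo(co, labs)
    ref <- MASS::lda(co, grouping = labs, CV = TRUE)
    expect_equal(as.character(ours$predicted), as.character(ref$class))
  })
})

test_that("lda_loo tolerates degenerate directions through its ridge", {
  co <- cbind(c(rnorm(20, 0, 0.1), rnorm(20, 3, 0.1)), rep(1, 40))  # constant dim 2
  labs <- rep(c("a", "b"), each = 20)
  fit <- lda_loo(co, labs)
  expect_equal(fit$accuracy, 1.0)
  expect_error(lda_loo(co, rep("a", 40)), "2 classes")
  expect_error(lda_loo(co, c("b", rep("a", 39))), "2 members")
})
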