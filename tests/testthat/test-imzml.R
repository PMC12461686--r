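make_imzml_fixture <- function(mode, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # 2x2 raster with one "peak" at 500 Da riding on a flat background
  axis <- c(499.996, 499.998, 500.000, 500.002, 500.004)
  vals <- rbind(c(0, 1, 10, 1, 0),
                c(0, 2, 20, 2, 0),
                c(0, 3, 30, 3, 0),
                c(0, 4, 40, 4, 0))
  x <- feature_matrix(vals, axis, sample_ids = paste0("p", 1:4))
  geom <- pixel_geometry(c(1, 2, 1, 2), c(1, 1, 2, 2))
  path <- file.path(dir, paste0("fixture_", mode, ".imzML"))
  write_imzml(x, geom, path, mode = mode)
  list(path = path, x = x, geom = geom, axis = axis, vals = vals)
}

test_that("continuous imzML fixtures round-trip", {
  f <- make_imzml_fixture("continuous")
  got <- read_imzml(f$path)
  expect_equal(unname(unclass(got$matrix)), unname(f$vals), ignore_attr = TRUE)
  expect_equal(feature_axis(got$matrix), f$axis)
  expect_equal(got$geometry$x, f$geom$x)
  expect_equal(got$geometry$y, f$geom$y)
})

test_that("processed-mode and continuous-mode files of identical content bin identically", {
  fc <- make_imzml_fixture("continuous")
  fp <- make_imzml_fixture("processed")
  edges <- seq(499.995, 500.005, by = 0.002)
  a <- read_imzml(fc$path, bin_edges = edges)
  b <- read_imzml(fp$path, bin_edges = edges)
  expect_equal(unclass(a$matrix), unclass(b$matrix), ignore_attr = TRUE)
  expect_equal(feature_axis(a$matrix), feature_axis(b$matrix))
  # the peak's intensity mass lands in the bin containing 500.000
  peak_bin <- findInterval(500.000, edges)
  expect_equal(unclass(a$matrix)[, peak_bin], c(10, 20, 30, 40), ignore_attr = TRUE)
})

test_that("pixels missing from the raster are simply absent and errors are explicit", {
  dir <- withr::local_tempdir()
  axis <- c(100, 200)
  x <- feature_matrix(rbind(c(1, 2), c(3, 4), c(5, 6)), axis)
  geom <- pixel_geometry(c(1, 2, 1), c(1, 1, 2), image_shape = c(2, 2))  # (2,2) missing
  path <- file.path(dir, "sparse.imzML")
  write_imzml(x, geom, path)
  got <- read_imzml(path)
  expect_equal(nrow(got$matrix), 3)
  expect_equal(nrow(got$geometry), 3)

  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "ibd")
})

test_that("rebin_spectrum performs interpolated rebinning onto a uniform grid", {
  # already on a uniform 0.002 grid: identity
  mz <- seq(100, 100.01, by = 0.002)
  int <- c(1, 5, 2, 8, 3, 7)
  got <- rebin_spectrum(mz, int, 0.002)
  expect_equal(got$mz, mz, tolerance = 1e-12)
  expect_equal(got$intensity, int, tolerance = 1e-12)

  got2 <- rebin_spectrum(c(100.000, 100.004), c(0, 4), 0.002)
  expect_equal(got2$mz, c(100.000, 100.002, 100.004))
  expect_equal(got2$intensity, c(0, 2, 4))

  withr::with_seed(31, {
    mz3 <- sort(runif(40, 200, 201))
    int3 <- rexp(40)
    got3 <- rebin_spectrum(mz3, int3, 0.01)
    expect_equal(got3$intensity, interp_oracle(mz3, int3, got3$mz), tolerance = 1e-9)
  })

  expect_error(rebin_spectrum(100, 1, 0.002), "at least 2")
})

test_that("ion_image integrates intensities across the peak window", {
  axis <- c(100, 200, 300)
  vals <- rbind(c(1, 10, 100), c(2, 20, 200), c(3, 30, 300), c(4, 40, 400))
  x <- feature_matrix(vals, axis)
  geom <- pixel_geometry(c(1, 2, 1, 2), c(1, 1, 2, 2))

  img1 <- ion_image(x, geom, c(150, 250))  # single feature
  expect_equal(img1, rbind(c(10, 20), c(30, 40)))

  img_all <- ion_image(x, geom, c(0, 1000))  # total ion count
  expect_equal(img_all, rbind(c(111, 222), c(333, 444)))

  img2 <- ion_image(x, geom, c(100, 200))  # two of three features, hand sums
  expect_equal(img2, rbind(c(11, 22), c(33, 44)))

  expect_warning(img0 <- ion_image(x, geom, c(500, 600)), "all-zero")
  expect_equal(img0, matrix(0, 2, 2))
})
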