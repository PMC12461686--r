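# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# textbook Pearson correlation from raw sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Rand index by explicit enumeration of all sample pairs
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    total <- total + 1L
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1L
  }
  agree / total
}

# all set partitions of 1..n as restricted-growth label vectors
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    k <- length(labels) + 1L
    if (k > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (v in seq_len(next_max)) recurse(c(labels, v), max(next_max, v + 1L))
  }
  recurse(integer(0), 1L)
  out
}

# piecewise-linear interpolation by explicit segment search
interp_oracle <- function(x, y, xout) {
  vapply(xout, function(q) {
    if (q <= x[1]) return(y[1])
    if (q >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= q))
    if (x[i] == q) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

# rank-based AUROC (Wilcoxon statistic)
auroc <- function(scores, truth) {
  r <- rank(scores)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# small clustered fixture shared by embedding / netmap tests
two_cluster_matrix <- function(n = 300L, p = 40L, sep = 4, seed = 42L) {
  withr::with_seed(seed, {
    half <- n %/% 2L
    mu1 <- rnorm(p); mu2 <- mu1 + sep / sqrt(p) * sample(c(-1, 1), p, TRUE)
    x <- rbind(
      matrix(rnorm(half * p, 0, 0.3), half, p) + matrix(mu1, half, p, byrow = TRUE),
      matrix(rnorm((n - half) * p, 0, 0.3), n - half, p) + matrix(mu2, n - half, p, byrow = TRUE))
    feature_matrix(exp(x), sort(runif(p, 100, 900)),
                   group_labels = factor(rep(1:2, c(half, n - half))))
  })
}
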