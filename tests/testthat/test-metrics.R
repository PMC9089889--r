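test_that("mmd equals the brute-force triple-sum oracle", {
  set.seed(1)
  # identical two-point sets: hand-checkable degenerate case
  v <- matrix(rnorm(6), 2, 3)
  m_id <- mmd(v, v, bandwidth = 1.3)
  expect_equal(as.numeric(m_id), mmd_oracle(v, v, 1.3), tolerance = 1e-12)
  expect_lte(as.numeric(m_id), 0)   # unbiased estimator dips below 0 here

  # random sizes and dimensions up to 10
  for (trial in 1:5) {
    n <- sample(2:10, 1); m <- sample(2:10, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d); Y <- matrix(rnorm(m * d) + 1, m, d)
    bw <- runif(1, 0.5, 3)
    expect_equal(as.numeric(mmd(X, Y, bw)), mmd_oracle(X, Y, bw),
                 tolerance = 1e-12)
  }
})

test_that("mmd is symmetric, permutation-invariant and size-guarded", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4); Y <- matrix(rnorm(32), 8, 4)
  expect_equal(as.numeric(mmd(X, Y, 1)), as.numeric(mmd(Y, X, 1)),
               tolerance = 1e-14)
  expect_equal(as.numeric(mmd(X[sample(10), ], Y, 1)),
               as.numeric(mmd(X, Y[sample(8), ], 1)), tolerance = 1e-14)
  expect_error(mmd(X[1, , drop = FALSE], Y), "at least 2")
  expect_error(mmd(X, Y, bandwidth = 0), "positive")
  expect_error(mmd(X, Y[, 1:2]), "dimension")
})

test_that("mmd separates distributions: same-law pairs score below shifted pairs", {
  hits <- 0L
  for (trial in 1:100) {
    set.seed(trial)
    a <- matrix(rnorm(50), ncol = 1); b <- matrix(rnorm(50), ncol = 1)
    c_ <- matrix(rnorm(50, mean = 3), ncol = 1)
    bw <- 1
    hits <- hits + (abs(mmd(a, b, bw)) < abs(mmd(a, c_, bw)))
  }
  expect_gte(hits, 95L)
})

test_that("exact DTW matches the exhaustive warping-path oracle", {
  expect_identical(dtw_exact(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(dtw_exact(c(0, 1), c(0, 1, 1), cost = "absolute"), 0)
  set.seed(3)
  for (trial in 1:20) {
    x <- sample(0:9, sample(2:6, 1), replace = TRUE)
    y <- sample(0:9, sample(2:6, 1), replace = TRUE)
    expect_equal(dtw_exact(x, y), dtw_oracle(x, y, squared = TRUE),
                 tolerance = 1e-12)
    expect_equal(dtw_exact(x, y, "absolute"), dtw_oracle(x, y, squared = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(dtw_exact(numeric(0), 1:3), "empty")
})

test_that("DTW with squared cost never exceeds the pointwise distance", {
  set.seed(4)
  for (trial in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    expect_lte(dtw_exact(x, y), sum((x - y)^2))   # diagonal path admissible
  }
})

test_that("approximate DTW degenerates to exact at full radius", {
  set.seed(5)
  x <- rnorm(100); y <- rnorm(120)
  expect_identical(dtw_approx(x, x, radius = 1), 0)
  expect_equal(dtw_approx(x, y, radius = 120), dtw_exact(x, y),
               tolerance = 1e-9)
  expect_equal(dtw_approx(x, y, radius = 120, cost = "absolute"),
               dtw_exact(x, y, cost = "absolute"), tolerance = 1e-9)
  expect_error(dtw_approx(x, y, radius = -1), "radius")
})

test_that("approximate DTW stays close to exact on smooth series", {
  # 100 random smooth pairs at N = 256, radius 1: the approximation is an
  # upper bound and its median inflation stays modest
  set.seed(6)
  ratios <- vapply(1:100, function(i) {
    x <- as.numeric(stats::filter(rnorm(276), rep(1 / 20, 20), sides = 1))[21:276]
    y <- as.numeric(stats::filter(rnorm(276), rep(1 / 20, 20), sides = 1))[21:276]
    ex <- dtw_exact(x, y)
    ap <- dtw_approx(x, y, radius = 1)
    expect_gte(ap, ex - 1e-9)
    ap / ex
  }, numeric(1))
  expect_lte(median(ratios), 1.2)
})

test_that("amplitude histograms integrate to one and detect level structure", {
  rec <- cached_record(duration = 0.5, seed = 2)
  h <- amplitude_histogram(rec)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)

  expect_equal(as.numeric(histogram_distance(rec$raw, rec$raw)), 0)
  expect_error(histogram_distance(rep(1, 5), rep(1, 5)), "zero-width")

  # a record resembles its own second half more than a half-conductance twin
  m <- two_state_model()
  r1 <- sample_trajectory(m, duration = 2, seed = 21)
  m2 <- two_state_model(unitary_current = -2.5)
  r2 <- sample_trajectory(m2, duration = 2, seed = 21)
  n <- length(r1$raw)
  d_self <- histogram_distance(r1$raw[1:(n / 2)], r1$raw[(n / 2 + 1):n])
  d_shift <- histogram_distance(r1$raw[1:(n / 2)], r2$raw[(n / 2 + 1):n])
  expect_lt(d_self, d_shift)
})

test_that("the fidelity report is deterministic and self-consistent", {
  rec <- cached_record(duration = 0.5, seed = 2)
  b <- make_windows(rec, W = 64, stride = 64)
  sp <- split_batch(b, 20)
  r1 <- evaluate_fidelity(sp$train, sp$holdout, seed = 7)
  r2 <- evaluate_fidelity(sp$train, sp$holdout, seed = 7)
  expect_identical(r1$mmd, r2$mmd)
  expect_identical(r1$dtw, r2$dtw)
  expect_gte(r1$dtw, 0)
  expect_true(r1$histogram_distance >= 0 && r1$histogram_distance <= 1)
  expect_gt(r1$parameters$bandwidth, 0)
})
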