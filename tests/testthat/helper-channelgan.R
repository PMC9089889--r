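# Shared fixtures: all synthetic, built in code at test time.

two_state_model <- function(...) demo_gating_model(...)

# C1 <-> C2 <-> O chain used for the linear-algebra oracle checks.
three_state_model <- function(k12 = 100, k21 = 50, k23 = 20, k32 = 200, ...) {
  Q <- matrix(c(-k12,        k12,        0,
                k21, -(k21 + k23),      k23,
                0,          k32,      -k32), 3, 3, byrow = TRUE)
  gating_model(Q, open_count = c(0L, 0L, 1L),
               state_names = c("C1", "C2", "O"), ...)
}

# Noise-free, unfiltered variant for exact-value checks.
clean_model <- function(base = two_state_model()) {
  base$noise_sd <- 0
  base$filter_cutoff <- NULL
  base
}

# Cached simulated record so several test files can share one simulation.
cached_record <- local({
  cache <- new.env(parent = emptyenv())
  function(duration = 2, seed = 1, model = two_state_model()) {
    key <- paste(duration, seed, format(model$noise_sd), sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- sample_trajectory(model, duration, seed = seed)
    }
    cache[[key]]
  }
})

# Split a window batch into train/holdout by index.
split_batch <- function(batch, n_train) {
  n <- dim(batch$data)[1]
  stopifnot(n > n_train)
  train <- batch; train$data <- batch$data[seq_len(n_train), , , drop = FALSE]
  hold <- batch; hold$data <- batch$data[(n_train + 1):n, , , drop = FALSE]
  list(train = train, holdout = hold)
}

# Two-peak detection on an all-points amplitude histogram: TRUE when the
# density has two local maxima separated by a valley at most 60% of the
# smaller peak.
is_bimodal <- function(x, n_bins = 25) {
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  d <- h$density
  # light smoothing to suppress single-bin jitter
  d <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  d[is.na(d)] <- 0
  peaks <- which(diff(sign(diff(d))) == -2) + 1
  peaks <- peaks[d[peaks] >= 0.1 * max(d)]
  if (length(peaks) < 2) return(FALSE)
  top2 <- peaks[order(d[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- min(d[lo:hi])
  valley <= 0.6 * min(d[top2])
}

# Brute-force MMD oracle: explicit double loops over Eq.-style sums.
mmd_oracle <- function(X, Y, bandwidth) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * bandwidth^2))
  n <- nrow(X); m <- nrow(Y)
  sxx <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) sxx <- sxx + k(X[i, ], X[j, ])
  }
  sxy <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) sxy <- sxy + k(X[i, ], Y[j, ])
  syy <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) syy <- syy + k(Y[i, ], Y[j, ])
  }
  sxx / (n * (n - 1)) - 2 * sxy / (m * n) + syy / (m * (m - 1))
}

# Exhaustive DTW oracle: walks every monotone warping path from (1,1) to
# (N,M) (steps right, down, diagonal), sums the local costs along each, and
# returns the minimum. Exponential, so only for N, M <= 6.
dtw_oracle <- function(x, y, squared = TRUE) {
  f <- function(a, b) if (squared) (a - b)^2 else abs(a - b)
  N <- length(x); M <- length(y)
  walk <- function(i, j, acc) {
    acc <- acc + f(x[i], y[j])
    if (i == N && j == M) return(acc)
    min(c(if (i < N) walk(i + 1, j, acc),
          if (j < M) walk(i, j + 1, acc),
          if (i < N && j < M) walk(i + 1, j + 1, acc)))
  }
  walk(1, 1, 0)
}
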