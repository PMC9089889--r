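#' Unbiased maximum mean discrepancy with a Gaussian kernel
#'
#' The kernel two-sample statistic comparing the distribution of real and
#' generated windows. For samples \eqn{\{x_i\}_{i=1..n}} and
#' \eqn{\{y_j\}_{j=1..m}} the unbiased estimator is
#' \deqn{\frac{1}{n(n-1)}\sum_i\sum_{j \ne i} K(x_i,x_j)
#'       - \frac{2}{mn}\sum_i\sum_j K(x_i,y_j)
#'       + \frac{1}{m(m-1)}\sum_i\sum_{j \ne i} K(y_i,y_j)}
#' with \eqn{K(a,b) = \exp(-\|a-b\|^2 / (2\sigma^2))}. Smaller values mean the
#' two distributions are more similar; the unbiased estimator can dip slightly
#' below zero for identical distributions.
#'
#' @param X n x d matrix (rows are flattened windows) or numeric vector
#' @param Y m x d matrix or numeric vector, same d
#' @param bandwidth Gaussian kernel sigma; default is the median pairwise
#'   Euclidean distance over the pooled sample (the median heuristic)
#' @return scalar MMD estimate with the bandwidth used attached as attribute
#'   `"bandwidth"`
#' @export
mmd <- function(X, Y, bandwidth = NULL) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  n <- nrow(X); m <- nrow(Y)
  if (n < 2 || m < 2) stop("mmd needs at least 2 points per sample (n = ",
                           n, ", m = ", m, ")")
  if (ncol(X) != ncol(Y)) stop("X and Y must have equal dimension")
  if (is.null(bandwidth)) bandwidth <- median_bandwidth(rbind(X, Y))
  if (bandwidth <= 0) stop("bandwidth must be positive")
  gauss_gram <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * bandwidth^2))
  }
  Kxx <- gauss_gram(X, X); Kyy <- gauss_gram(Y, Y); Kxy <- gauss_gram(X, Y)
  val <- (sum(Kxx) - n) / (n * (n - 1)) -
    2 * sum(Kxy) / (m * n) +
    (sum(Kyy) - m) / (m * (m - 1))
  structure(val, bandwidth = bandwidth)
}

# Median pairwise Euclidean distance (median heuristic for the kernel width).
median_bandwidth <- function(Z) {
  d <- stats::dist(Z)
  bw <- median(d)
  if (!is.finite(bw) || bw <= 0) bw <- mean(d) + 1e-12
  bw
}

#' Exact dynamic time warping distance
#'
#' Fills the N x M accumulated-cost matrix by the recurrence
#' `D[i, j] = f(x[i], y[j]) + min(D[i, j-1], D[i-1, j], D[i-1, j-1])`
#' (first row and column accumulate) and returns the terminal cost — the
#' minimal accumulated local cost over all monotone alignments of the two
#' series. With either cost, `dtw_exact(x, x) = 0`.
#'
#' @param x,y numeric series (length >= 1)
#' @param cost local cost `f`: `"squared"` difference (default) or
#'   `"absolute"` difference
#' @return scalar accumulated cost
#' @export
dtw_exact <- function(x, y, cost = c("squared", "absolute")) {
  cost <- match.arg(cost)
  if (length(x) == 0 || length(y) == 0) stop("empty series")
  cpp_dtw(as.numeric(x), as.numeric(y), cost == "squared")
}

#' Approximate dynamic time warping (coarsen-project-refine)
#'
#' The multiresolution approximation: the series are recursively halved by
#' averaging adjacent pairs, the optimal path is found at the coarse
#' resolution, projected up, inflated by `radius` cells, and refined by a
#' banded exact DTW inside that corridor. With `radius >= max(N, M)` the band
#' covers the whole matrix and the result equals [dtw_exact()]. The
#' approximation never undercuts the exact distance (it optimizes over a
#' subset of alignments).
#'
#' @param x,y numeric series
#' @param radius corridor half-width in cells (default 1)
#' @inheritParams dtw_exact
#' @return scalar accumulated cost
#' @export
dtw_approx <- function(x, y, radius = 1L, cost = c("squared", "absolute")) {
  cost <- match.arg(cost)
  if (length(x) == 0 || length(y) == 0) stop("empty series")
  if (radius < 0) stop("radius must be >= 0")
  fastdtw_rec(as.numeric(x), as.numeric(y), as.integer(radius),
              cost == "squared")$cost
}

fastdtw_rec <- function(x, y, radius, squared) {
  N <- length(x); M <- length(y)
  min_size <- radius + 2L
  if (N <= min_size || M <= min_size) {
    return(cpp_dtw_band(x, y, rep(1L, N), rep(M, N), squared))
  }
  coarse <- fastdtw_rec(coarsen_series(x), coarsen_series(y), radius, squared)
  band <- expand_path_band(coarse$i, coarse$j, N, M, radius)
  cpp_dtw_band(x, y, band$lo, band$hi, squared)
}

coarsen_series <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) x <- c(x, x[n])
  0.5 * (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)])
}

# Inflate a coarse warping path by `radius` cells (in coarse space, in both
# directions — the standard multiresolution-DTW window), then project onto
# the fine grid, where each coarse cell covers a 2x2 block. The coarse path
# is monotone, so the per-row bounds are monotone and consecutive rows'
# bands always connect.
expand_path_band <- function(pi, pj, N, M, radius) {
  Nc <- max(pi); Mc <- max(pj)
  loc <- rep(NA_integer_, Nc); hic <- rep(NA_integer_, Nc)
  for (k in seq_along(pi)) {
    i <- pi[k]; j <- pj[k]
    if (is.na(loc[i])) { loc[i] <- j; hic[i] <- j }
    else { loc[i] <- min(loc[i], j); hic[i] <- max(hic[i], j) }
  }
  if (radius > 0) {
    lo2 <- loc; hi2 <- hic
    for (i in seq_len(Nc)) {
      nb <- max(1L, i - radius):min(Nc, i + radius)
      lo2[i] <- min(loc[nb]); hi2[i] <- max(hic[nb])
    }
    loc <- pmax(1L, lo2 - radius); hic <- pmin(Mc, hi2 + radius)
  }
  fine_i <- pmin(pmax(ceiling(seq_len(N) / 2), 1L), Nc)
  list(lo = as.integer(pmax(1L, 2L * loc[fine_i] - 1L)),
       hi = as.integer(pmin(M, 2L * hic[fine_i])))
}

#' All-points amplitude histogram
#'
#' The histogram over every raw-current sample of a record; its modes sit at
#' the conductance levels (baseline, baseline + unitary current, ...). Bin
#' widths default to the Freedman–Diaconis rule.
#'
#' @param record a [paired_record()] or a numeric vector of current samples
#' @param breaks passed to [graphics::hist()]: a breaks vector, a count, or a
#'   rule name (default `"FD"`)
#' @return list with `mids`, `breaks`, `density` (integrates to 1) and
#'   `counts`, of class `amplitude_histogram`
#' @export
amplitude_histogram <- function(record, breaks = "FD") {
  x <- if (inherits(record, "paired_record")) record$raw else as.numeric(record)
  if (length(x) < 1) stop("need at least one sample")
  if (diff(range(x)) == 0) {
    # single support point: one unit-mass bin
    eps <- max(1e-9, abs(x[1]) * 1e-9)
    breaks <- c(x[1] - eps, x[1] + eps)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(mids = h$mids, breaks = h$breaks, density = h$density,
                 counts = h$counts),
            class = "amplitude_histogram")
}

#' Histogram intersection distance between two amplitude distributions
#'
#' Both samples are binned on a shared grid (Freedman–Diaconis on the pooled
#' data by default) and compared by `1 - sum(min(p1, p2))` over bin masses:
#' 0 for identical histograms, 1 for disjoint supports.
#'
#' @param x,y records or numeric vectors of current samples
#' @param breaks shared bin specification (default `"FD"` on the pooled data)
#' @return distance in `[0, 1]`, with the shared breaks as attribute
#'   `"breaks"`
#' @export
histogram_distance <- function(x, y, breaks = "FD") {
  vx <- if (inherits(x, "paired_record")) x$raw else as.numeric(x)
  vy <- if (inherits(y, "paired_record")) y$raw else as.numeric(y)
  pooled <- c(vx, vy)
  if (diff(range(pooled)) == 0) {
    stop("zero-width bin range: all samples identical")
  }
  grid <- graphics::hist(pooled, breaks = breaks, plot = FALSE)$breaks
  hx <- graphics::hist(vx, breaks = grid, plot = FALSE)
  hy <- graphics::hist(vy, breaks = grid, plot = FALSE)
  px <- hx$counts / sum(hx$counts)
  py <- hy$counts / sum(hy$counts)
  structure(1 - sum(pmin(px, py)), breaks = grid)
}

#' Fidelity report comparing real and generated window batches
#'
#' Bundles the three similarity measures on a pair of window batches: the
#' unbiased Gaussian-kernel MMD over flattened windows, the mean DTW over
#' randomly paired raw rows, and the amplitude-histogram intersection distance
#' over all raw-row samples. All parameter choices (kernel bandwidth, DTW cost
#' and pairing seed, bin grid) are recorded in the report.
#'
#' @param real,generated `window_batch` objects with equal window length
#' @param bandwidth MMD kernel bandwidth (default: median heuristic)
#' @param dtw_pairs number of random real/generated pairs averaged for the DTW
#'   figure (default 25)
#' @param dtw_radius corridor radius for [dtw_approx()] (default 1)
#' @param cost DTW local cost (default squared difference)
#' @param seed seed for the DTW pairing
#' @return object of class `metric_report`: list of `mmd`, `dtw`,
#'   `histogram_distance`, and `parameters`
#' @export
evaluate_fidelity <- function(real, generated, bandwidth = NULL,
                              dtw_pairs = 25L, dtw_radius = 1L,
                              cost = "squared", seed = 1L) {
  stopifnot(inherits(real, "window_batch"), inherits(generated, "window_batch"))
  if (dim(real$data)[3] != dim(generated$data)[3]) {
    stop("window lengths differ between batches")
  }
  m <- mmd(flatten_windows(real), flatten_windows(generated), bandwidth)
  nr <- dim(real$data)[1]; ng <- dim(generated$data)[1]
  dtws <- with_seed(seed, {
    ir <- sample.int(nr, dtw_pairs, replace = dtw_pairs > nr)
    ig <- sample.int(ng, dtw_pairs, replace = dtw_pairs > ng)
    vapply(seq_len(dtw_pairs), function(k) {
      dtw_approx(real$data[ir[k], 1, ], generated$data[ig[k], 1, ],
                 radius = dtw_radius, cost = cost)
    }, numeric(1))
  })
  hd <- histogram_distance(as.vector(real$data[, 1, ]),
                           as.vector(generated$data[, 1, ]))
  structure(list(
    mmd = as.numeric(m), dtw = mean(dtws),
    histogram_distance = as.numeric(hd),
    parameters = list(bandwidth = attr(m, "bandwidth"),
                      dtw_pairs = dtw_pairs, dtw_radius = dtw_radius,
                      dtw_cost = cost, pairing_seed = seed,
                      n_real = nr, n_generated = ng,
                      breaks = attr(hd, "breaks"))),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n",
      "  MMD (unbiased, Gaussian kernel): ", format(x$mmd, digits = 5),
      "  [bandwidth ", format(x$parameters$bandwidth, digits = 4), "]\n",
      "  mean DTW over ", x$parameters$dtw_pairs, " pairs: ",
      format(x$dtw, digits = 5), "\n",
      "  amplitude-histogram distance: ",
      format(x$histogram_distance, digits = 5), "\n", sep = "")
  invisible(x)
}
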