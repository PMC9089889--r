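#' Jointly embed real and generated windows in two dimensions
#'
#' Windows from the two datasets are concatenated into one "super dataset" and
#' embedded together (never per-group, so the two clouds share one
#' coordinate system), then tagged with their group identity for the
#' downstream [cluster_separation_test()]. By default only the raw row of
#' each window enters the embedding; set `rows = "both"` to flatten both rows.
#'
#' Two methods are offered: `"tsne"`, an exact t-distributed stochastic
#' neighbour embedding (perplexity-calibrated Gaussian affinities in the input
#' space, Student-t affinities in the plane, KL divergence minimized by
#' gradient descent with momentum and early exaggeration — quadratic in the
#' number of windows, fine at the window counts used here), and `"pca"`, the
#' first two principal components (linear, deterministic, fast).
#'
#' @param real,generated `window_batch` objects windowed identically (the
#'   conventional embedding width is 512 samples); each must contribute at
#'   least 10 windows
#' @param method `"tsne"` or `"pca"`
#' @param seed integer seed (t-SNE initialization)
#' @param rows `"raw"` (default) or `"both"`
#' @param perplexity t-SNE perplexity (default 30, capped at (P-1)/3)
#' @param max_iter t-SNE gradient iterations (default 500)
#' @return object of class `embedding_result`: `coords` (P x 2), `group`
#'   (factor), `method`, `seed`, `window_length`
#' @export
embed_windows <- function(real, generated, method = c("tsne", "pca"),
                          seed = 1L, rows = c("raw", "both"),
                          perplexity = 30, max_iter = 500L) {
  method <- match.arg(method); rows <- match.arg(rows)
  stopifnot(inherits(real, "window_batch"), inherits(generated, "window_batch"))
  if (dim(real$data)[3] != dim(generated$data)[3]) {
    stop("the two datasets must be windowed identically")
  }
  take <- function(b) {
    if (rows == "raw") {
      d <- dim(b$data); matrix(b$data[, 1, ], d[1], d[3])
    } else flatten_windows(b)
  }
  Xr <- take(real); Xg <- take(generated)
  if (nrow(Xr) < 10 || nrow(Xg) < 10) {
    stop("need at least 10 windows per group (got ", nrow(Xr), " and ",
         nrow(Xg), ")")
  }
  X <- rbind(Xr, Xg)
  group <- factor(rep(c("real", "generated"), c(nrow(Xr), nrow(Xg))))
  coords <- switch(method,
    pca = {
      pc <- prcomp(X, rank. = 2, center = TRUE, scale. = FALSE)
      unname(pc$x[, 1:2, drop = FALSE])
    },
    tsne = tsne_embed(X, perplexity = perplexity, max_iter = max_iter,
                      seed = seed))
  structure(list(coords = coords, group = group, method = method,
                 seed = seed, window_length = dim(real$data)[3]),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", nrow(x$coords), " points (",
      paste(table(x$group), collapse = " + "), "), method ", x$method,
      ", W = ", x$window_length, "\n", sep = "")
  invisible(x)
}

# Exact t-SNE (quadratic): suitable for the few hundred windows used here.
tsne_embed <- function(X, perplexity = 30, max_iter = 500L, seed = 1L,
                       lr = 100, momentum_switch = 250L,
                       exaggeration_iters = 100L) {
  P_n <- nrow(X)
  perplexity <- max(2, min(perplexity, (P_n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2

  # per-point precision calibrated to the target perplexity (binary search)
  Pmat <- matrix(0, P_n, P_n)
  logU <- log(perplexity)
  for (i in seq_len(P_n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    Pmat[i, -i] <- p / sum(p)
  }
  Pj <- (Pmat + t(Pmat)) / (2 * P_n)
  Pj <- pmax(Pj, 1e-12)

  with_seed(seed, {
    Y <- matrix(rnorm(P_n * 2, sd = 1e-4), P_n, 2)
    V <- matrix(0, P_n, 2)
    gains <- matrix(1, P_n, 2)
    for (it in seq_len(max_iter)) {
      Pe <- if (it <= exaggeration_iters) Pj * 4 else Pj
      d2 <- as.matrix(stats::dist(Y))^2
      num <- 1 / (1 + d2); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      mom <- if (it <= momentum_switch) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(V), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      V <- mom * V - lr * gains * grad
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y), "-")
    }
    Y
  })
}
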