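#' Permutation test of cluster separation between two embedded groups
#'
#' Asks whether the two labelled point clouds of an embedding are more
#' separable than chance. The observed statistic is the mean out-of-fold
#' accuracy of a linear separator (least-squares linear discriminant on the
#' 2-D coordinates) over stratified 5-fold cross-validation. The null
#' distribution is built by permuting the group labels `n_permutations` times
#' (at least 1000 by default) and recomputing the statistic; the p-value uses
#' the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`,
#' so perfectly separated clouds attain the minimum `1 / (1 + n_permutations)`.
#'
#' Degenerate embeddings with all points identical return chance accuracy 0.5
#' and `p = 1`.
#'
#' @param emb an `embedding_result` from [embed_windows()], or any list with
#'   `coords` (P x 2 matrix) and `group` (factor with exactly two levels)
#' @param n_permutations number of label permutations (default 1000)
#' @param n_folds cross-validation folds (default 5)
#' @param seed integer seed for fold assignment and permutations
#' @return object of class `cluster_test_result`: `statistic`, `null_stats`,
#'   `p_value`, `n_permutations`
#' @export
cluster_separation_test <- function(emb, n_permutations = 1000L, n_folds = 5L,
                                    seed = 1L) {
  coords <- as.matrix(emb$coords)
  group <- factor(emb$group)
  if (nlevels(group) != 2L) {
    stop("exactly two groups required, got ", nlevels(group))
  }
  if (nrow(coords) != length(group)) stop("coords/group length mismatch")
  if (all(apply(coords, 2, function(v) diff(range(v)) == 0))) {
    return(structure(list(statistic = 0.5, null_stats = numeric(0),
                          p_value = 1, n_permutations = 0L),
                     class = "cluster_test_result"))
  }
  y <- as.integer(group) - 1L

  with_seed(seed, {
    folds <- stratified_folds(y, n_folds)
    obs <- cv_linear_accuracy(coords, y, folds)
    null_stats <- vapply(seq_len(n_permutations), function(p) {
      yp <- sample(y)
      cv_linear_accuracy(coords, yp, stratified_folds(yp, n_folds))
    }, numeric(1))
    p_value <- (1 + sum(null_stats >= obs)) / (1 + n_permutations)
    structure(list(statistic = obs, null_stats = null_stats,
                   p_value = p_value,
                   n_permutations = as.integer(n_permutations)),
              class = "cluster_test_result")
  })
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("<cluster_test_result> separation accuracy ",
      format(x$statistic, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

# Stratified fold labels: each class is split as evenly as possible.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

# Mean held-out accuracy of a least-squares linear discriminant
# (ridge-stabilized so degenerate folds never error).
cv_linear_accuracy <- function(X, y, folds) {
  X1 <- cbind(1, X)
  acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2L) return(0.5)
    A <- crossprod(X1[tr, , drop = FALSE]) + diag(1e-8, ncol(X1))
    b <- crossprod(X1[tr, , drop = FALSE], y[tr])
    beta <- solve(A, b)
    pred <- as.numeric(X1[te, , drop = FALSE] %*% beta > 0.5)
    mean(pred == y[te])
  }, numeric(1))
  mean(acc)
}
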