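# Helpers building small embeddings and window batches.

gauss_embedding <- function(n_per = 25, sep = 0, seed = 1) {
  set.seed(seed)
  coords <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
                  matrix(rnorm(n_per * 2, mean = sep), ncol = 2))
  list(coords = coords,
       group = factor(rep(c("a", "b"), each = n_per)))
}

batch_from_model <- function(model, duration = 0.6, seed = 1, W = 32) {
  rec <- sample_trajectory(model, duration = duration, seed = seed)
  make_windows(rec, W = W, stride = W)
}

test_that("joint embedding keeps one row per window and is seed-stable", {
  b1 <- batch_from_model(two_state_model(), seed = 31)
  b2 <- batch_from_model(two_state_model(), seed = 32)
  emb <- embed_windows(b1, b2, method = "tsne", seed = 5, max_iter = 120)
  expect_identical(nrow(emb$coords),
                   dim(b1$data)[1] + dim(b2$data)[1])
  expect_identical(as.vector(table(emb$group)),
                   c(dim(b2$data)[1], dim(b1$data)[1]))
  emb2 <- embed_windows(b1, b2, method = "tsne", seed = 5, max_iter = 120)
  expect_identical(emb$coords, emb2$coords)      # determinism contract
  emb3 <- embed_windows(b1, b2, method = "pca", seed = 5)
  expect_identical(nrow(emb3$coords), nrow(emb$coords))

  short <- b1; short$data <- b1$data[1:5, , , drop = FALSE]
  expect_error(embed_windows(short, b2), "at least 10")
})

test_that("grossly different phenotypes separate significantly end-to-end", {
  # 5x the unitary current and 10x the gating rates, at a noise level that
  # does not drown the smaller channel (0.3 pA vs its 1 pA amplitude)
  slow_big <- demo_gating_model(noise_sd = 0.3)
  fast_small <- demo_gating_model(k_co = 500, k_oc = 1000,
                                  unitary_current = -1, noise_sd = 0.3)
  rec_a <- sample_trajectory(slow_big, duration = 1, seed = 33)
  rec_b <- sample_trajectory(fast_small, duration = 1, seed = 34)
  # a shared scaler keeps the two phenotypes in common units, as when
  # comparing datasets rather than a record against its own synthesis
  sc <- robust_scale(rec_a)$scaler
  a <- make_windows(rec_a, W = 32, stride = 32, scaler = sc)
  b <- make_windows(rec_b, W = 32, stride = 32, scaler = sc)
  emb <- embed_windows(a, b, method = "tsne", seed = 2)
  ct <- cluster_separation_test(emb, n_permutations = 1000, seed = 3)
  expect_lte(ct$p_value, 0.01)
})

test_that("random labels on one cloud are rarely declared separated", {
  rejections <- 0L
  for (seed in 1:20) {
    emb <- gauss_embedding(n_per = 25, sep = 0, seed = seed)
    ct <- cluster_separation_test(emb, n_permutations = 199, seed = seed)
    rejections <- rejections + (ct$p_value <= 0.05)
  }
  expect_lte(rejections, 2L)    # p > 0.05 in >= 18/20 null runs
})

test_that("perfect separation saturates the statistic and the add-one p", {
  emb <- gauss_embedding(n_per = 25, sep = 10, seed = 4)
  ct <- cluster_separation_test(emb, n_permutations = 1000, seed = 5)
  expect_identical(ct$statistic, 1)
  expect_identical(ct$p_value, 1 / 1001)
  expect_identical(ct$n_permutations, 1000L)
  expect_length(ct$null_stats, 1000L)
  # p is the add-one count rule
  expect_identical(ct$p_value,
                   (1 + sum(ct$null_stats >= ct$statistic)) / 1001)
})

test_that("the test is invariant to group names and rigid rotations", {
  emb <- gauss_embedding(n_per = 20, sep = 2, seed = 6)
  ct1 <- cluster_separation_test(emb, n_permutations = 300, seed = 7)
  relabeled <- emb
  relabeled$group <- factor(ifelse(emb$group == "a", "z1", "z0"))
  ct2 <- cluster_separation_test(relabeled, n_permutations = 300, seed = 7)
  expect_identical(ct1$p_value, ct2$p_value)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rotated <- emb; rotated$coords <- emb$coords %*% R
  ct3 <- cluster_separation_test(rotated, n_permutations = 300, seed = 7)
  expect_equal(ct1$statistic, ct3$statistic, tolerance = 1e-12)
})

test_that("degenerate embeddings give chance accuracy and p = 1", {
  emb <- list(coords = matrix(0, 40, 2),
              group = factor(rep(c("a", "b"), 20)))
  ct <- cluster_separation_test(emb)
  expect_identical(ct$statistic, 0.5)
  expect_identical(ct$p_value, 1)
  three <- list(coords = matrix(rnorm(60), ncol = 2),
                group = factor(rep(c("a", "b", "c"), 10)))
  expect_error(cluster_separation_test(three), "two groups")
})

test_that("embed + test on same-phenotype splits controls the type-I rate", {
  # both "groups" are disjoint records of the same phenotype: rejections at
  # alpha = 0.05 must stay <= 0.10 over 50 repetitions (the embedding induces
  # mild dependence between points, hence the loose bound)
  rejections <- 0L
  for (rep_i in 1:50) {
    a <- batch_from_model(two_state_model(), duration = 0.35,
                          seed = 100 + 2 * rep_i, W = 32)
    b <- batch_from_model(two_state_model(), duration = 0.35,
                          seed = 101 + 2 * rep_i, W = 32)
    emb <- embed_windows(a, b, method = "pca", seed = rep_i)
    ct <- cluster_separation_test(emb, n_permutations = 199, seed = rep_i)
    rejections <- rejections + (ct$p_value <= 0.05)
  }
  expect_lte(rejections / 50, 0.10)
})
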