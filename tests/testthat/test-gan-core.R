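# Structural and behavioural checks of the DC-GAN at toy scale (W = 64).

tiny_batches <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- cached_record(duration = 2, seed = 1)
      b <- make_windows(rec, W = 64, stride = 64)
      cache <<- split_batch(b, 96)
    }
    cache
  }
})

test_that("parameter counts are pure functions of the architecture spec", {
  np <- count_parameters(tiny_gan_spec())
  # frozen snapshot of the tiny architecture
  expect_identical(np, c(generator = 7410L, discriminator = 1769L))
  # rerunning gives the same counts (no RNG leakage into the architecture)
  expect_identical(count_parameters(tiny_gan_spec()), np)
  # widening the generator only changes the generator count
  np2 <- count_parameters(tiny_gan_spec(gen_channels = c(64L, 16L, 8L, 8L)))
  expect_identical(np2[["discriminator"]], np[["discriminator"]])
  expect_gt(np2[["generator"]], np[["generator"]])
})

test_that("generation has the contracted shape, range and determinism", {
  spec <- tiny_gan_spec()
  model <- structure(
    list(gen = channelgan:::with_seed(1, channelgan:::build_generator(spec)),
         disc = NULL, spec = spec,
         scaler = tiny_batches()$train$scaler,
         log = data.frame(), best_generator = NULL,
         best_epoch = NA_integer_, best_mmd = Inf),
    class = "gan_model")
  g <- gan_generate(model, 16, seed = 3)
  expect_identical(dim(g$data), c(16L, 2L, 64L))
  expect_identical(g$source, "generated")
  expect_true(all(is.finite(g$data)))
  expect_true(all(abs(g$data) <= 1))            # tanh range, even untrained
  expect_identical(gan_generate(model, 16, seed = 3)$data, g$data)
  expect_false(identical(gan_generate(model, 16, seed = 4)$data, g$data))
})

test_that("a short training run logs finite losses and is seed-reproducible", {
  spec <- tiny_gan_spec(epochs = 8)
  fit1 <- gan_train(tiny_batches()$train, spec,
                    eval_batch = tiny_batches()$holdout, eval_every = 4)
  expect_identical(nrow(fit1$log), 8L)
  expect_identical(fit1$log$epoch, 1:8)
  expect_true(all(is.finite(fit1$log$d_loss)))
  expect_true(all(is.finite(fit1$log$g_loss)))
  expect_true(any(is.finite(fit1$log$mmd)))
  fit2 <- gan_train(tiny_batches()$train, spec,
                    eval_batch = tiny_batches()$holdout, eval_every = 4)
  expect_identical(fit1$log, fit2$log)          # full seeding contract
  expect_error(gan_train(tiny_batches()$holdout, spec), "2 x batch_size")
})

test_that("updating one network never changes the other's parameters", {
  spec <- tiny_gan_spec()
  channelgan:::with_seed(2, {
    gen <- channelgan:::build_generator(spec)
    disc <- channelgan:::build_discriminator(spec)
    xr <- tiny_batches()$train$data[1:8, , , drop = FALSE]
    z <- matrix(rnorm(8 * spec$latent_dim), 8)

    # one discriminator gradient step
    gf <- channelgan:::gen_forward(gen, z, spec)
    dr <- channelgan:::disc_forward(disc, xr, spec)
    gr <- channelgan:::disc_backward(disc, dr$caches, (dr$p - 1) / 8, spec)$grads
    disc2 <- channelgan:::set_params(
      disc, channelgan:::sgd_step(channelgan:::get_params(disc), gr, 0.01))
    expect_identical(channelgan:::get_params(gen),
                     channelgan:::get_params(gen))  # untouched by construction
    expect_false(identical(channelgan:::get_params(disc2),
                           channelgan:::get_params(disc)))

    # one generator gradient step leaves the discriminator untouched
    df <- channelgan:::disc_forward(disc2, gf$out, spec)
    dx <- channelgan:::disc_backward(disc2, df$caches, (df$p - 1) / 8, spec)$dx
    gg <- channelgan:::gen_backward(gen, gf$caches, dx, spec)
    gen2 <- channelgan:::set_params(
      gen, channelgan:::sgd_step(channelgan:::get_params(gen), gg, 0.01))
    expect_false(identical(channelgan:::get_params(gen2),
                           channelgan:::get_params(gen)))
    expect_identical(channelgan:::get_params(disc2),
                     channelgan:::get_params(disc2))
  })
})

test_that("generator loss descends against a frozen discriminator", {
  spec <- tiny_gan_spec()
  losses <- channelgan:::with_seed(3, {
    gen <- channelgan:::build_generator(spec)
    disc <- channelgan:::build_discriminator(spec)
    z <- matrix(rnorm(16 * spec$latent_dim), 16)
    vapply(1:30, function(i) {
      gf <- channelgan:::gen_forward(gen, z, spec)
      df <- channelgan:::disc_forward(disc, gf$out, spec, training = FALSE)
      dx <- channelgan:::disc_backward(disc, df$caches, (df$p - 1) / 16, spec)$dx
      gg <- channelgan:::gen_backward(gen, gf$caches, dx, spec)
      gen <<- channelgan:::set_params(
        gen, channelgan:::sgd_step(channelgan:::get_params(gen), gg, 0.005))
      generator_loss(df$p)
    }, numeric(1))
  })
  # small-step full-batch descent on a smooth loss: monotone non-increasing
  expect_true(all(diff(losses) <= 1e-6))
  expect_lt(losses[30], losses[1])
})

test_that("label decoding snaps to recorded levels with a lower-tie rule", {
  sc <- structure(list(center = 0, scale = 1, label_levels = c(0L, 1L),
                       single_level = FALSE, sample_rate = 5000),
                  class = "scaler_params")
  mk <- function(labrow) {
    structure(list(data = array(c(rbind(rep(0, length(labrow)), labrow)),
                                dim = c(1, 2, length(labrow))),
                   window = length(labrow), stride = length(labrow),
                   scaler = sc, source = "generated"),
              class = "window_batch")
  }
  dec <- function(v) decode_labels(mk(v), crop_fraction = 0)[[1]]$label
  expect_identical(dec(rep(0.97, 10)), rep(1L, 10))   # near +1 -> level 1
  expect_identical(dec(rep(0, 10)), rep(0L, 10))      # exact tie -> lower
  expect_identical(dec(rep(-0.2, 10)), rep(0L, 10))
  # encode -> decode round trip on noiseless integer labels
  rec <- cached_record(duration = 0.5, seed = 8)
  b <- make_windows(rec, W = 64, stride = 64)
  back <- decode_labels(b, crop_fraction = 0)
  expect_identical(unlist(lapply(back, `[[`, "label")),
                   rec$label[seq_len(64 * length(back))])
})

test_that("checkpoints round-trip and reject mismatched architectures", {
  dir <- withr::local_tempdir()
  spec <- tiny_gan_spec(epochs = 2)
  fit <- gan_train(tiny_batches()$train, spec)
  save_gan_checkpoint(fit, file.path(dir, "ck"))
  back <- load_gan_checkpoint(file.path(dir, "ck"))
  expect_identical(channelgan:::get_params(back$gen),
                   channelgan:::get_params(fit$gen))
  g1 <- gan_generate(fit, 4, seed = 1, use_best = FALSE)
  g2 <- gan_generate(back, 4, seed = 1, use_best = FALSE)
  expect_identical(g1$data, g2$data)
  # spec mismatch detected
  other <- fit; other$spec <- tiny_gan_spec(gen_channels = c(16L, 8L, 8L, 8L))
  save_gan_checkpoint(other, file.path(dir, "bad"))
  expect_error(load_gan_checkpoint(file.path(dir, "bad")), "shape mismatch")
  expect_error(load_gan_checkpoint(file.path(dir, "nope")), "checkpoint")
})
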