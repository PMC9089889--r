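#' Specify the DC-GAN architecture and training hyperparameters
#'
#' The generator maps a latent noise vector through a dense stack to a coarse
#' (channels x W/8) feature map, then through three transposed-convolution
#' upsampling stages (kernel 4, stride 2), each followed by batch normalization
#' and LeakyReLU, and finally a same-length convolution to the 2-row output
#' with a tanh activation — so generated windows live in `[-1, 1]`, matching
#' the scaled training windows. The discriminator is the mirror image: three
#' strided convolutions with LeakyReLU, dropout 0.3 after every convolution
#' except the input layer (no batch normalization on the discriminator side),
#' then flatten and a single sigmoid unit. Both networks are trained with Adam.
#'
#' @param window window length W in samples; must be divisible by 8 (three
#'   2x upsampling stages). Default 1280.
#' @param latent_dim length of the flat latent noise vector (default 128). Set
#'   `latent_shape = "image"` to instead draw a 2 x W latent field that the
#'   dense stack consumes flattened.
#' @param latent_shape `"vector"` (default) or `"image"` (2 x W latent noise)
#' @param gen_channels integer vector of length 4: channels of the dense-stage
#'   feature map and of the three deconvolution stages.
#' @param disc_channels integer vector of length 3: channels of the three
#'   strided convolutions.
#' @param kernel convolution/deconvolution kernel width (default 4)
#' @param dropout discriminator dropout rate (default 0.3)
#' @param learning_rate Adam learning rate, default 1e-4
#' @param beta1 Adam first-moment decay (default 0.5, the DC-GAN convention)
#' @param batch_size minibatch size (default 64)
#' @param epochs training epochs
#' @param seed integer seed controlling initialization, shuffling, latent
#'   draws and dropout
#' @return object of class `gan_spec`
#' @export
gan_spec <- function(window = 1280L, latent_dim = 128L,
                     latent_shape = c("vector", "image"),
                     gen_channels = c(128L, 64L, 32L, 16L),
                     disc_channels = c(16L, 32L, 64L),
                     kernel = 4L, dropout = 0.3,
                     learning_rate = 1e-4, beta1 = 0.5,
                     batch_size = 64L, epochs = 200L, seed = 1L) {
  latent_shape <- match.arg(latent_shape)
  window <- as.integer(window)
  if (window %% 8L != 0L) stop("window must be divisible by 8")
  stopifnot(length(gen_channels) == 4, length(disc_channels) == 3,
            dropout >= 0, dropout < 1, learning_rate > 0, batch_size >= 1)
  if (latent_shape == "image") latent_dim <- 2L * window
  structure(list(window = window, rows = 2L,
                 latent_dim = as.integer(latent_dim),
                 latent_shape = latent_shape,
                 gen_channels = as.integer(gen_channels),
                 disc_channels = as.integer(disc_channels),
                 kernel = as.integer(kernel), dropout = dropout,
                 learning_rate = learning_rate, beta1 = beta1,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "gan_spec")
}

# A compact spec sized for CPU smoke runs and examples.
#' Tiny GAN configuration for quick CPU demonstrations
#'
#' A scaled-down [gan_spec()] (W = 64, small channel counts, batch 32,
#' learning rate 1e-3) that trains in minutes on one CPU core while exercising
#' the full architecture. Used by examples, the demo pipeline and the test
#' suite.
#' @param ... overrides passed to [gan_spec()]
#' @return a `gan_spec`
#' @export
tiny_gan_spec <- function(...) {
  args <- modifyList(list(window = 64L, latent_dim = 16L,
                          gen_channels = c(32L, 16L, 8L, 8L),
                          disc_channels = c(8L, 16L, 16L),
                          batch_size = 32L, epochs = 200L,
                          learning_rate = 1e-3, seed = 1L),
                     list(...))
  do.call(gan_spec, args)
}

# ---- network construction -------------------------------------------------

build_generator <- function(spec) {
  W <- spec$window; g <- spec$gen_channels; k <- spec$kernel
  L0 <- W %/% 8L
  list(dense = dense_init(spec$latent_dim, g[1] * L0),
       bn0 = bn_init(g[1]),
       dc1 = deconv_init(g[1], g[2], k, 2L, 1L), bn1 = bn_init(g[2]),
       dc2 = deconv_init(g[2], g[3], k, 2L, 1L), bn2 = bn_init(g[3]),
       dc3 = deconv_init(g[3], g[4], k, 2L, 1L), bn3 = bn_init(g[4]),
       conv = conv_init(g[4], spec$rows, 5L, 1L, 2L))
}

build_discriminator <- function(spec) {
  d <- spec$disc_channels; k <- spec$kernel
  L3 <- spec$window %/% 8L
  list(c1 = conv_init(spec$rows, d[1], k, 2L, 1L),
       c2 = conv_init(d[1], d[2], k, 2L, 1L),
       c3 = conv_init(d[2], d[3], k, 2L, 1L),
       dense = dense_init(d[3] * L3, 1L))
}

trainable_names <- function(ly) {
  switch(ly$type, dense = , conv = , deconv = c("W", "b"),
         bn = c("gamma", "beta"), character(0))
}
get_params <- function(net) lapply(net, function(ly) ly[trainable_names(ly)])
set_params <- function(net, params) {
  for (nm in names(params)) for (p in names(params[[nm]])) {
    net[[nm]][[p]] <- params[[nm]][[p]]
  }
  net
}

#' Number of trainable parameters of a GAN network pair
#'
#' @param spec a [gan_spec()]
#' @return named vector with `generator` and `discriminator` counts
#' @export
count_parameters <- function(spec) {
  cnt <- function(net) sum(vapply(get_params(net), function(ps)
    sum(vapply(ps, length, 1L)), 1L))
  with_seed(0L, {  # initialization draws must not disturb the caller's RNG
    gen <- build_generator(spec); disc <- build_discriminator(spec)
    c(generator = cnt(gen), discriminator = cnt(disc))
  })
}

# ---- forward / backward ---------------------------------------------------

gen_forward <- function(gen, z, spec, training = TRUE) {
  N <- nrow(z); L0 <- spec$window %/% 8L; g <- spec$gen_channels
  caches <- list()
  f <- dense_fwd(gen$dense, z); caches$dense <- f$cache
  x <- array(f$out, dim = c(N, L0, g[1]))
  x <- aperm(x, c(1, 3, 2))                      # N x c0 x L0
  b <- bn_fwd(gen$bn0, x, training); gen$bn0 <- b$layer; caches$bn0 <- b$cache
  a <- lrelu_fwd(b$out); caches$a0 <- a$cache; x <- a$out
  for (i in 1:3) {
    dc <- paste0("dc", i); bn <- paste0("bn", i); ac <- paste0("a", i)
    f <- deconv_fwd(gen[[dc]], x); caches[[dc]] <- f$cache
    b <- bn_fwd(gen[[bn]], f$out, training)
    gen[[bn]] <- b$layer; caches[[bn]] <- b$cache
    a <- lrelu_fwd(b$out); caches[[ac]] <- a$cache; x <- a$out
  }
  f <- conv_fwd(gen$conv, x); caches$conv <- f$cache
  th <- tanh_fwd(f$out); caches$tanh <- th$cache
  list(out = th$out, caches = caches, gen = gen)
}

gen_backward <- function(gen, caches, dout, spec) {
  N <- dim(dout)[1]; L0 <- spec$window %/% 8L; g <- spec$gen_channels
  grads <- list()
  d <- tanh_bwd(caches$tanh, dout)
  bk <- conv_bwd(gen$conv, caches$conv, d); grads$conv <- bk$grads; d <- bk$dx
  for (i in 3:1) {
    dc <- paste0("dc", i); bn <- paste0("bn", i); ac <- paste0("a", i)
    d <- lrelu_bwd(caches[[ac]], d)
    bk <- bn_bwd(gen[[bn]], caches[[bn]], d); grads[[bn]] <- bk$grads; d <- bk$dx
    bk <- deconv_bwd(gen[[dc]], caches[[dc]], d); grads[[dc]] <- bk$grads
    d <- bk$dx
  }
  d <- lrelu_bwd(caches$a0, d)
  bk <- bn_bwd(gen$bn0, caches$bn0, d); grads$bn0 <- bk$grads; d <- bk$dx
  d2 <- matrix(aperm(d, c(1, 3, 2)), N, L0 * g[1])
  bk <- dense_bwd(gen$dense, caches$dense, d2); grads$dense <- bk$grads
  grads[names(get_params(gen))]
}

disc_forward <- function(disc, x, spec, training = TRUE) {
  caches <- list()
  f <- conv_fwd(disc$c1, x); caches$c1 <- f$cache
  a <- lrelu_fwd(f$out); caches$a1 <- a$cache; x <- a$out
  for (i in 2:3) {
    cv <- paste0("c", i); ac <- paste0("a", i); dr <- paste0("d", i)
    f <- conv_fwd(disc[[cv]], x); caches[[cv]] <- f$cache
    a <- lrelu_fwd(f$out); caches[[ac]] <- a$cache
    dp <- dropout_fwd(a$out, spec$dropout, training)
    caches[[dr]] <- dp$cache; x <- dp$out
  }
  dims <- dim(x); caches$flat_dims <- dims
  x2 <- matrix(x, dims[1], dims[2] * dims[3])
  f <- dense_fwd(disc$dense, x2); caches$dense <- f$cache
  p <- sigmoid_fwd(f$out)
  list(p = as.vector(p$out), logits = as.vector(f$out), caches = caches)
}

disc_backward <- function(disc, caches, dlogits, spec) {
  grads <- list()
  bk <- dense_bwd(disc$dense, caches$dense, matrix(dlogits, ncol = 1))
  grads$dense <- bk$grads
  d <- array(bk$dx, dim = caches$flat_dims)
  for (i in 3:2) {
    cv <- paste0("c", i); ac <- paste0("a", i); dr <- paste0("d", i)
    d <- dropout_bwd(caches[[dr]], d)
    d <- lrelu_bwd(caches[[ac]], d)
    bk <- conv_bwd(disc[[cv]], caches[[cv]], d); grads[[cv]] <- bk$grads
    d <- bk$dx
  }
  d <- lrelu_bwd(caches$a1, d)
  bk <- conv_bwd(disc$c1, caches$c1, d); grads$c1 <- bk$grads
  list(grads = grads[names(get_params(disc))], dx = bk$dx)
}

# ---- losses ---------------------------------------------------------------

#' Binary cross-entropy loss
#'
#' `L = -[y log p + (1 - y) log(1 - p)]`, averaged over the batch, with
#' predictions clipped to `[1e-7, 1 - 1e-7]` for numerical safety. This is the
#' adversarial loss both networks train against: the true label says whether a
#' window is real or generated, the prediction is the discriminator's class
#' probability.
#'
#' @param y true labels in `{0, 1}` (recycled against `p`)
#' @param p predicted probabilities
#' @return mean loss, a non-negative scalar
#' @export
bce_loss <- function(y, p) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Adversarial losses of the two networks
#'
#' The discriminator loss is the binary cross-entropy computed twice and
#' totalled — once against the real windows (true label 1) and once against
#' the generated windows (true label 0). The generator loss is the
#' non-saturating form: the cross-entropy of the discriminator's predictions
#' on generated windows against a true label of 1 (the generator "wants" its
#' output classified real).
#'
#' @param real_preds discriminator probabilities on real windows
#' @param fake_preds discriminator probabilities on generated windows
#' @return scalar loss
#' @export
discriminator_loss <- function(real_preds, fake_preds) {
  bce_loss(1, real_preds) + bce_loss(0, fake_preds)
}

#' @rdname discriminator_loss
#' @export
generator_loss <- function(fake_preds) bce_loss(1, fake_preds)

# ---- training -------------------------------------------------------------

#' Train the DC-GAN on a batch of scaled windows
#'
#' Alternates one discriminator update and one generator update per minibatch.
#' The discriminator sees a real minibatch and an equally sized generated
#' minibatch; gradients flow from the clipped binary cross-entropy through the
#' sigmoid logits. The generator update backpropagates the non-saturating
#' generator loss through a (non-updated) discriminator into the generator.
#' All randomness — initialization, shuffling, latent draws, dropout masks —
#' derives from `spec$seed`, so a rerun with the same spec and data reproduces
#' the loss sequences exactly.
#'
#' If `eval_batch` is given, the maximum mean discrepancy between generated
#' windows and that held-out batch is computed every `eval_every` epochs; the
#' generator snapshot with the lowest evaluation MMD is retained as
#' `best_generator` (mirroring manual early stopping: adversarial training can
#' deteriorate if left to run).
#'
#' @param batch a `window_batch` from [make_windows()]
#' @param spec a [gan_spec()] with `spec$window` matching the batch
#' @param eval_batch optional held-out `window_batch` for MMD tracking
#' @param eval_every epochs between MMD evaluations (default 10)
#' @param checkpoint_dir optional directory; a checkpoint is written every
#'   `checkpoint_every` epochs and at the best evaluation MMD
#' @param checkpoint_every epochs between checkpoints (default 50)
#' @param augment_fraction per-epoch Gaussian augmentation of the raw row as a
#'   fraction of its peak-to-peak amplitude (default 0.001, i.e. ~0.1%);
#'   0 disables
#' @param verbose print a line every 10 epochs
#' @return object of class `gan_model`: the trained networks, the spec, the
#'   batch's scaler, the per-epoch loss log (`$log`), and `best_generator` /
#'   `best_epoch` when evaluation was enabled
#' @export
gan_train <- function(batch, spec, eval_batch = NULL, eval_every = 10L,
                      checkpoint_dir = NULL, checkpoint_every = 50L,
                      augment_fraction = 0.001, verbose = FALSE) {
  stopifnot(inherits(batch, "window_batch"), inherits(spec, "gan_spec"))
  N <- dim(batch$data)[1]
  if (dim(batch$data)[3] != spec$window) {
    stop("batch window length ", dim(batch$data)[3],
         " does not match spec window ", spec$window)
  }
  if (N < 2L * spec$batch_size) {
    stop("need at least 2 x batch_size = ", 2L * spec$batch_size,
         " windows, got ", N)
  }

  with_seed(spec$seed, {
    gen <- build_generator(spec)
    disc <- build_discriminator(spec)
    opt_g <- adam_init(get_params(gen), lr = spec$learning_rate,
                       beta1 = spec$beta1)
    opt_d <- adam_init(get_params(disc), lr = spec$learning_rate,
                       beta1 = spec$beta1)
    bs <- spec$batch_size
    n_batches <- N %/% bs
    log <- data.frame(epoch = integer(), d_loss = numeric(),
                      g_loss = numeric(), mmd = numeric())
    best_mmd <- Inf; best_gen <- NULL; best_epoch <- NA_integer_

    eval_flat <- if (!is.null(eval_batch)) flatten_windows(eval_batch)

    for (epoch in seq_len(spec$epochs)) {
      ep_batch <- if (augment_fraction > 0) {
        augment_windows(batch, augment_fraction,
                        seed = NULL)  # inside the seeded stream
      } else batch
      ord <- sample.int(N)
      d_losses <- g_losses <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        idx <- ord[((b - 1) * bs + 1):(b * bs)]
        xr <- ep_batch$data[idx, , , drop = FALSE]

        # --- discriminator step ---
        z <- matrix(rnorm(bs * spec$latent_dim), bs, spec$latent_dim)
        gf <- gen_forward(gen, z, spec, training = TRUE); gen <- gf$gen
        dr <- disc_forward(disc, xr, spec, training = TRUE)
        df <- disc_forward(disc, gf$out, spec, training = TRUE)
        d_losses[b] <- discriminator_loss(dr$p, df$p)
        gr_r <- disc_backward(disc, dr$caches, (dr$p - 1) / bs, spec)$grads
        gr_f <- disc_backward(disc, df$caches, (df$p - 0) / bs, spec)$grads
        grads_d <- mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                          gr_r, gr_f, SIMPLIFY = FALSE)
        st <- adam_step(opt_d, get_params(disc), grads_d)
        opt_d <- st$opt; disc <- set_params(disc, st$params)

        # --- generator step ---
        z <- matrix(rnorm(bs * spec$latent_dim), bs, spec$latent_dim)
        gf <- gen_forward(gen, z, spec, training = TRUE); gen <- gf$gen
        df <- disc_forward(disc, gf$out, spec, training = TRUE)
        g_losses[b] <- generator_loss(df$p)
        dx <- disc_backward(disc, df$caches, (df$p - 1) / bs, spec)$dx
        grads_g <- gen_backward(gen, gf$caches, dx, spec)
        st <- adam_step(opt_g, get_params(gen), grads_g)
        opt_g <- st$opt; gen <- set_params(gen, st$params)
      }
      d_ep <- mean(d_losses); g_ep <- mean(g_losses)
      if (!is.finite(d_ep) || !is.finite(g_ep)) {
        warning("non-finite loss at epoch ", epoch,
                "; aborting with last good state")
        break
      }
      mmd_ep <- NA_real_
      if (!is.null(eval_batch) && (epoch %% eval_every == 0L ||
                                   epoch == spec$epochs)) {
        gb <- generate_from(gen, spec, n = dim(eval_batch$data)[1],
                            batch$scaler, training_stats = FALSE)
        mmd_ep <- mmd(flatten_windows(gb), eval_flat)
        if (mmd_ep < best_mmd) {
          best_mmd <- mmd_ep; best_gen <- gen; best_epoch <- epoch
          if (!is.null(checkpoint_dir)) {
            save_gan_checkpoint(
              list(gen = gen, disc = disc, spec = spec,
                   scaler = batch$scaler, epoch = epoch),
              file.path(checkpoint_dir, "best"))
          }
        }
      }
      log <- rbind(log, data.frame(epoch = epoch, d_loss = d_ep,
                                   g_loss = g_ep, mmd = mmd_ep))
      if (!is.null(checkpoint_dir) && epoch %% checkpoint_every == 0L) {
        save_gan_checkpoint(
          list(gen = gen, disc = disc, spec = spec,
               scaler = batch$scaler, epoch = epoch),
          file.path(checkpoint_dir, sprintf("epoch-%05d", epoch)))
      }
      if (verbose && epoch %% 10L == 0L) {
        message(sprintf("epoch %4d  D %.4f  G %.4f%s", epoch, d_ep, g_ep,
                        if (is.na(mmd_ep)) "" else sprintf("  MMD %.4g", mmd_ep)))
      }
    }

    structure(list(gen = gen, disc = disc, spec = spec,
                   scaler = batch$scaler, log = log,
                   best_generator = best_gen, best_epoch = best_epoch,
                   best_mmd = best_mmd),
              class = "gan_model")
  })
}

#' @export
print.gan_model <- function(x, ...) {
  np <- count_parameters(x$spec)
  cat("<gan_model> W =", x$spec$window, "| G params", np["generator"],
      "| D params", np["discriminator"], "|", nrow(x$log), "epochs trained\n")
  if (!is.na(x$best_epoch)) {
    cat("  best evaluation MMD", format(x$best_mmd, digits = 4),
        "at epoch", x$best_epoch, "\n")
  }
  invisible(x)
}

flatten_windows <- function(batch) {
  d <- dim(batch$data)
  matrix(batch$data, d[1], d[2] * d[3])
}

generate_from <- function(gen, spec, n, scaler, training_stats = FALSE) {
  z <- matrix(rnorm(n * spec$latent_dim), n, spec$latent_dim)
  out <- gen_forward(gen, z, spec, training = training_stats)$out
  structure(list(data = out, window = spec$window, stride = spec$window,
                 scaler = scaler, source = "generated"),
            class = "window_batch")
}

#' Generate labelled windows from a trained (or checkpointed) generator
#'
#' @param model a `gan_model` from [gan_train()], or a checkpoint directory
#'   path written by [save_gan_checkpoint()]
#' @param n_windows number of 2 x W windows to draw
#' @param seed integer seed; identical (model, seed) pairs give identical
#'   output
#' @param use_best use the minimum-evaluation-MMD generator snapshot if one
#'   was recorded (default TRUE)
#' @return a `window_batch` with `source = "generated"`, values in `[-1, 1]`
#' @export
gan_generate <- function(model, n_windows, seed = NULL, use_best = TRUE) {
  if (is.character(model)) model <- load_gan_checkpoint(model)
  stopifnot(inherits(model, "gan_model"))
  gen <- if (use_best && !is.null(model$best_generator)) {
    model$best_generator
  } else model$gen
  with_seed(seed,
    generate_from(gen, model$spec, n_windows, model$scaler,
                  training_stats = FALSE))
}

#' Decode generated windows into physical-unit labelled records
#'
#' Inverse of the preprocessing chain: each window's edges are cropped (the
#' transposed convolutions' boundary artefacts live there), the raw row is
#' mapped back to picoamperes with the training scaler, and the continuous
#' label row is snapped to the nearest integer level recorded in the scaler
#' (exact ties resolve to the lower level).
#'
#' @param batch a `window_batch` (typically `source = "generated"`)
#' @param scaler a `scaler_params`; defaults to the batch's own
#' @param crop_fraction edge crop per side before decoding (default 0.05)
#' @return list of [paired_record()] objects, one per window
#' @export
decode_labels <- function(batch, scaler = batch$scaler, crop_fraction = 0.05) {
  stopifnot(inherits(batch, "window_batch"), inherits(scaler, "scaler_params"))
  cropped <- crop_edges(batch, crop_fraction)
  n <- dim(cropped$data)[1]
  lapply(seq_len(n), function(i) {
    inverse_scale(cropped$data[i, , ], scaler, snap_labels = TRUE)
  })
}

#' Save / load a GAN checkpoint directory
#'
#' A checkpoint is a directory holding the two networks' parameter arrays, the
#' `gan_spec` and the training scaler, each serialized separately so a
#' checkpoint can resume training or drive [gan_generate()].
#'
#' @param state list with `gen`, `disc`, `spec`, `scaler` (and optionally
#'   `epoch`), or a `gan_model`
#' @param dir checkpoint directory (created if needed)
#' @return `dir` (save) or a `gan_model` (load)
#' @export
save_gan_checkpoint <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(state$gen, file.path(dir, "generator.rds"))
  saveRDS(state$disc, file.path(dir, "discriminator.rds"))
  saveRDS(state$spec, file.path(dir, "spec.rds"))
  saveRDS(state$scaler, file.path(dir, "scaler.rds"))
  saveRDS(state$epoch %||% NA_integer_, file.path(dir, "epoch.rds"))
  invisible(dir)
}

#' @rdname save_gan_checkpoint
#' @export
load_gan_checkpoint <- function(dir) {
  need <- file.path(dir, c("generator.rds", "discriminator.rds", "spec.rds",
                           "scaler.rds"))
  if (!all(file.exists(need))) {
    stop("not a checkpoint directory (missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "), "): ", dir)
  }
  gen <- readRDS(file.path(dir, "generator.rds"))
  spec <- readRDS(file.path(dir, "spec.rds"))
  # shape consistency between stored parameters and spec
  ref <- build_generator(spec)
  for (nm in names(ref)) {
    for (p in trainable_names(ref[[nm]])) {
      if (!identical(dim(ref[[nm]][[p]]) %||% length(ref[[nm]][[p]]),
                     dim(gen[[nm]][[p]]) %||% length(gen[[nm]][[p]]))) {
        stop("checkpoint/spec shape mismatch in generator layer '", nm, "'")
      }
    }
  }
  structure(list(gen = gen,
                 disc = readRDS(file.path(dir, "discriminator.rds")),
                 spec = spec,
                 scaler = readRDS(file.path(dir, "scaler.rds")),
                 log = data.frame(), best_generator = NULL,
                 best_epoch = NA_integer_, best_mmd = Inf),
            class = "gan_model")
}
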