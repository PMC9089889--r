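# Minimal neural-network primitives for the DC-GAN: dense, 1-D convolution,
# 1-D transposed convolution, batch normalization, LeakyReLU, tanh, sigmoid,
# dropout, and an Adam optimizer. Everything is plain R arrays; convolutions
# are evaluated as one matrix product per layer (im2col) so BLAS does the work.
# Shapes follow the (batch N, channels C, length L) convention.

nn_rnorm <- function(...) array(rnorm(prod(c(...)), sd = 0.02), dim = c(...))

# ---- dense ----
dense_init <- function(n_in, n_out) {
  list(type = "dense", W = nn_rnorm(n_in, n_out), b = numeric(n_out))
}
dense_fwd <- function(ly, x) {               # x: N x n_in
  list(out = sweep(x %*% ly$W, 2, ly$b, "+"), cache = x)
}
dense_bwd <- function(ly, cache, dout) {
  list(dx = dout %*% t(ly$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

# ---- 1-D convolution (stride s, zero pad p): im2col + GEMM ----
conv_init <- function(c_in, c_out, k, stride, pad) {
  list(type = "conv", W = nn_rnorm(c_in * k, c_out), b = numeric(c_out),
       c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad)
}

conv_out_len <- function(L, k, stride, pad) (L + 2 * pad - k) %/% stride + 1L

# patch matrix: (N*Lout) x (c_in*k); column (ci-1)*k + j holds x_pad[, ci, start+j-1]
im2col <- function(x, k, stride, pad) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  Lp <- L + 2L * pad
  xp <- array(0, dim = c(N, C, Lp))
  xp[, , (pad + 1L):(pad + L)] <- x
  Lout <- conv_out_len(L, k, stride, pad)
  starts <- (seq_len(Lout) - 1L) * stride + 1L
  cols <- matrix(0, N * Lout, C * k)
  for (ci in seq_len(C)) for (j in seq_len(k)) {
    cols[, (ci - 1L) * k + j] <- as.vector(xp[, ci, starts + j - 1L])
  }
  cols
}

col2im <- function(dcols, dims, k, stride, pad) {
  N <- dims[1]; C <- dims[2]; L <- dims[3]
  Lp <- L + 2L * pad
  Lout <- conv_out_len(L, k, stride, pad)
  starts <- (seq_len(Lout) - 1L) * stride + 1L
  dxp <- array(0, dim = c(N, C, Lp))
  for (ci in seq_len(C)) for (j in seq_len(k)) {
    idx <- starts + j - 1L
    dxp[, ci, idx] <- dxp[, ci, idx] +
      matrix(dcols[, (ci - 1L) * k + j], N, Lout)
  }
  dxp[, , (pad + 1L):(pad + L), drop = FALSE]
}

conv_fwd <- function(ly, x) {
  d <- dim(x); N <- d[1]; Lout <- conv_out_len(d[3], ly$k, ly$stride, ly$pad)
  cols <- im2col(x, ly$k, ly$stride, ly$pad)
  y2 <- sweep(cols %*% ly$W, 2, ly$b, "+")        # (N*Lout) x c_out
  out <- aperm(array(y2, dim = c(N, Lout, ly$c_out)), c(1, 3, 2))
  list(out = out, cache = list(cols = cols, dims = d))
}
conv_bwd <- function(ly, cache, dout) {
  d <- dim(dout); N <- d[1]; Lout <- d[3]
  dy2 <- matrix(aperm(dout, c(1, 3, 2)), N * Lout, ly$c_out)
  list(dx = col2im(dy2 %*% t(ly$W), cache$dims, ly$k, ly$stride, ly$pad),
       grads = list(W = crossprod(cache$cols, dy2), b = colSums(dy2)))
}

# ---- 1-D transposed convolution ----
# Forward scatters each input sample into a k-wide stencil every `stride`
# samples (the adjoint of conv's gather); Lout = stride*(L-1) + k - 2*pad.
deconv_init <- function(c_in, c_out, k, stride, pad) {
  list(type = "deconv", W = nn_rnorm(c_in, c_out * k), b = numeric(c_out),
       c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad)
}
deconv_out_len <- function(L, k, stride, pad) stride * (L - 1L) + k - 2L * pad

deconv_fwd <- function(ly, x) {
  d <- dim(x); N <- d[1]; L <- d[3]
  x2 <- matrix(aperm(x, c(1, 3, 2)), N * L, ly$c_in)
  P <- x2 %*% ly$W                                # (N*L) x (c_out*k)
  Lfull <- ly$stride * (L - 1L) + ly$k
  starts <- (seq_len(L) - 1L) * ly$stride + 1L
  ypad <- array(0, dim = c(N, ly$c_out, Lfull))
  for (co in seq_len(ly$c_out)) for (j in seq_len(ly$k)) {
    idx <- starts + j - 1L
    ypad[, co, idx] <- ypad[, co, idx] + matrix(P[, (co - 1L) * ly$k + j], N, L)
  }
  out <- ypad[, , (ly$pad + 1L):(Lfull - ly$pad), drop = FALSE]
  out <- sweep(out, 2, ly$b, "+")
  list(out = out, cache = list(x2 = x2, dims = d))
}
deconv_bwd <- function(ly, cache, dout) {
  d <- cache$dims; N <- d[1]; L <- d[3]
  Lfull <- ly$stride * (L - 1L) + ly$k
  dypad <- array(0, dim = c(N, ly$c_out, Lfull))
  dypad[, , (ly$pad + 1L):(Lfull - ly$pad)] <- dout
  starts <- (seq_len(L) - 1L) * ly$stride + 1L
  G <- matrix(0, N * L, ly$c_out * ly$k)          # gather of dypad patches
  for (co in seq_len(ly$c_out)) for (j in seq_len(ly$k)) {
    G[, (co - 1L) * ly$k + j] <- as.vector(dypad[, co, starts + j - 1L])
  }
  list(dx = aperm(array(G %*% t(ly$W), dim = c(N, L, ly$c_in)), c(1, 3, 2)),
       grads = list(W = crossprod(cache$x2, G),
                    b = colSums(matrix(aperm(dout, c(1, 3, 2)),
                                       N * dim(dout)[3], ly$c_out))))
}

# ---- batch normalization (per channel over batch x length) ----
bn_init <- function(C, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C),
       momentum = momentum, eps = eps)
}
bn_fwd <- function(ly, x, training) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  if (training) {
    mu <- apply(x, 2, mean)
    xc <- sweep(x, 2, mu, "-")
    v <- apply(xc^2, 2, mean)
    ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
    ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
  } else {
    mu <- ly$run_mean; v <- ly$run_var
    xc <- sweep(x, 2, mu, "-")
  }
  inv_sd <- 1 / sqrt(v + ly$eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, m = N * L),
       layer = ly)  # layer returned because running stats changed
}
bn_bwd <- function(ly, cache, dout) {
  xhat <- cache$xhat; inv_sd <- cache$inv_sd; m <- cache$m
  dgamma <- apply(dout * xhat, 2, sum)
  dbeta <- apply(dout, 2, sum)
  dxhat <- sweep(dout, 2, ly$gamma, "*")
  # standard batchnorm backward, vectorized per channel
  t1 <- sweep(dxhat, 2, apply(dxhat, 2, mean), "-")
  t2 <- sweep(xhat, 2, apply(dxhat * xhat, 2, mean), "*")
  dx <- sweep(t1 - t2, 2, inv_sd, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- activations / dropout ----
lrelu_fwd <- function(x, alpha = 0.2) {
  out <- ifelse(x > 0, x, alpha * x)
  list(out = out, cache = x > 0, alpha = alpha)
}
lrelu_bwd <- function(cache, dout, alpha = 0.2) dout * ifelse(cache, 1, alpha)

tanh_fwd <- function(x) { y <- tanh(x); list(out = y, cache = y) }
tanh_bwd <- function(cache, dout) dout * (1 - cache^2)

sigmoid_fwd <- function(x) { y <- 1 / (1 + exp(-x)); list(out = y, cache = y) }

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array(runif(length(x)) >= rate, dim = dim(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}
dropout_bwd <- function(cache, dout) if (is.null(cache)) dout else dout * cache

# ---- Adam ----
adam_init <- function(params, lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(layer)
    lapply(layer, function(p) array(0, dim = dim(p) %||% length(p))))
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zeros, v = zeros)
}

# params/grads: list (per layer) of lists of arrays with matching names.
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (li in seq_along(params)) {
    for (nm in names(params[[li]])) {
      g <- grads[[li]][[nm]]
      if (is.null(g)) next
      opt$m[[li]][[nm]] <- b1 * opt$m[[li]][[nm]] + (1 - b1) * g
      opt$v[[li]][[nm]] <- b2 * opt$v[[li]][[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[li]][[nm]] / corr1
      vhat <- opt$v[[li]][[nm]] / corr2
      params[[li]][[nm]] <- params[[li]][[nm]] -
        opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  list(opt = opt, params = params)
}

sgd_step <- function(params, grads, lr) {
  for (li in seq_along(params)) {
    for (nm in names(params[[li]])) {
      g <- grads[[li]][[nm]]
      if (is.null(g)) next
      params[[li]][[nm]] <- params[[li]][[nm]] - lr * g
    }
  }
  params
}
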