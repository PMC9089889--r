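#' Extract open and closed dwell times from an idealization
#'
#' Run-length encodes the label row into sojourns, aggregating all conducting
#' levels (label >= 1) into a single "open" class and label 0 into "closed" —
#' the standard single-channel kinetic workup. The first and last sojourns of
#' a record are censored (their true start/end fall outside the record) and
#' are excluded from fitting by default.
#'
#' @param record a [paired_record()]
#' @return object of class `dwell_set`: data frame with columns `class`
#'   (`"open"`/`"closed"`), `duration` (seconds), `censored`, plus the sample
#'   rate as an attribute
#' @export
extract_dwells <- function(record) {
  stopifnot(inherits(record, "paired_record"))
  cls <- ifelse(record$label >= 1L, "open", "closed")
  r <- rle(cls)
  n <- length(r$lengths)
  df <- data.frame(class = r$values,
                   duration = r$lengths / record$sample_rate,
                   censored = seq_len(n) %in% c(1L, n))
  structure(df, class = c("dwell_set", "data.frame"),
            sample_rate = record$sample_rate)
}

#' Pull the durations of one dwell class
#'
#' @param dwells a `dwell_set` from [extract_dwells()]
#' @param class `"open"` or `"closed"`
#' @param include_censored keep the censored first/last sojourns (default
#'   FALSE)
#' @return numeric vector of durations in seconds (possibly empty)
#' @export
dwell_durations <- function(dwells, class = c("open", "closed"),
                            include_censored = FALSE) {
  class <- match.arg(class)
  keep <- dwells$class == class & (include_censored | !dwells$censored)
  dwells$duration[keep]
}

#' Fit an exponential mixture to dwell times by maximum likelihood
#'
#' Dwell-time distributions under Markov gating are mixtures of exponentials,
#' \deqn{f(t) = \sum_k (w_k / \tau_k) \exp(-t / \tau_k),}
#' one component per underlying (aggregated) state. The fit is by
#' expectation-maximization with multistart: responsibilities in the E-step,
#' closed-form weight and time-constant updates in the M-step. The
#' log-likelihood is checked to be non-decreasing at every iteration. With
#' `K = 1` the MLE is the sample mean, recovered exactly.
#'
#' @param durations numeric vector of uncensored dwell durations (seconds),
#'   or a `dwell_set` (then `class` selects which durations)
#' @param K number of exponential components
#' @param class dwell class when `durations` is a `dwell_set`
#' @param n_starts number of random restarts (default 4)
#' @param max_iter EM iteration cap per start (default 200)
#' @param tol relative log-likelihood convergence tolerance (default 1e-8)
#' @param seed integer seed making the restarts reproducible
#' @return object of class `exp_mix_fit`: `K`, `taus` (seconds, ascending),
#'   `weights` (summing to 1), `log_likelihood`, `bic`, `converged`,
#'   `n` (number of dwells fitted)
#' @export
fit_exp_mixture <- function(durations, K, class = "open", n_starts = 4L,
                            max_iter = 200L, tol = 1e-8, seed = 1L) {
  if (inherits(durations, "dwell_set")) {
    durations <- dwell_durations(durations, class)
  }
  t <- as.numeric(durations)
  if (any(t <= 0)) stop("durations must be positive")
  n <- length(t)
  if (n < 10 * K) {
    stop("need at least ", 10 * K, " dwells to fit ", K,
         " components, got ", n)
  }
  if (K == 1L) {
    tau <- mean(t)
    ll <- sum(stats::dexp(t, 1 / tau, log = TRUE))
    return(structure(list(K = 1L, taus = tau, weights = 1,
                          log_likelihood = ll, bic = -2 * ll + log(n),
                          converged = TRUE, n = n),
                     class = "exp_mix_fit"))
  }

  with_seed(seed, {
    best <- NULL
    qs <- quantile(t, probs = (seq_len(K)) / (K + 1))
    for (s in seq_len(n_starts)) {
      taus <- pmax(as.numeric(qs) * exp(rnorm(K, 0, if (s == 1) 0 else 0.5)),
                   min(t) / 10)
      w <- rep(1 / K, K)
      ll_old <- -Inf; converged <- FALSE
      for (it in seq_len(max_iter)) {
        # E-step in log space for stability
        logd <- vapply(seq_len(K), function(k)
          log(w[k]) - log(taus[k]) - t / taus[k], numeric(n))
        mx <- apply(logd, 1, max)
        lse <- mx + log(rowSums(exp(logd - mx)))
        ll <- sum(lse)
        if (ll < ll_old - 1e-8) {
          stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
        }
        r <- exp(logd - lse)
        # M-step
        nk <- colSums(r)
        w <- nk / n
        taus <- colSums(r * t) / nk
        if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll)) {
          converged <- TRUE; ll_old <- ll; break
        }
        ll_old <- ll
      }
      if (is.null(best) || ll_old > best$ll) {
        best <- list(taus = taus, w = w, ll = ll_old, converged = converged)
      }
    }
    ord <- order(best$taus)
    n_par <- 2 * K - 1
    structure(list(K = as.integer(K), taus = best$taus[ord],
                   weights = best$w[ord] / sum(best$w),
                   log_likelihood = best$ll,
                   bic = -2 * best$ll + n_par * log(n),
                   converged = best$converged, n = n),
              class = "exp_mix_fit")
  })
}

#' @export
print.exp_mix_fit <- function(x, ...) {
  cat("<exp_mix_fit> K =", x$K, "on", x$n, "dwells",
      if (!x$converged) "(not converged)" else "", "\n")
  tab <- data.frame(tau_ms = x$taus * 1e3, weight = x$weights)
  print(tab, row.names = FALSE, digits = 4)
  cat("  logLik", format(x$log_likelihood, digits = 6),
      " BIC", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' Choose the number of exponential components by information criterion
#'
#' Fits mixtures with `K = 1..K_max` and returns the fit minimizing the
#' Bayesian information criterion (the default criterion used throughout the
#' dwell-time workup).
#'
#' @inheritParams fit_exp_mixture
#' @param K_max largest component count tried (default 4, capped so every fit
#'   keeps at least 10 dwells per component)
#' @return the winning `exp_mix_fit`, with the full criterion table attached
#'   as attribute `"ic_table"`
#' @export
select_K <- function(durations, K_max = 4L, class = "open", seed = 1L, ...) {
  if (inherits(durations, "dwell_set")) {
    durations <- dwell_durations(durations, class)
  }
  K_max <- min(K_max, length(durations) %/% 10L)
  if (K_max < 1L) stop("need at least 10 dwells, got ", length(durations))
  fits <- lapply(seq_len(K_max), function(k)
    fit_exp_mixture(durations, k, seed = seed, ...))
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.min(bics)]]
  attr(best, "ic_table") <- data.frame(
    K = seq_len(K_max), bic = bics,
    log_likelihood = vapply(fits, function(f) f$log_likelihood, numeric(1)))
  best
}

#' Log-binned dwell-time histogram (Sigworth–Sine style)
#'
#' Returns the square-root-ordinate, log-abscissa histogram conventionally
#' used to display dwell-time distributions with superimposed mixture fits,
#' where each exponential component appears as a peak at its time constant.
#' Display helper only; fitting uses the raw durations.
#'
#' @param durations numeric dwell durations (seconds)
#' @param bins_per_decade histogram resolution (default 10)
#' @param fit optional `exp_mix_fit` whose density is evaluated on the grid
#' @return list with `log10_t` bin mids, `sqrt_density`, and optionally
#'   `fit_sqrt_density`
#' @export
dwell_histogram <- function(durations, bins_per_decade = 10L, fit = NULL) {
  t <- as.numeric(durations)
  stopifnot(all(t > 0))
  lt <- log10(t)
  breaks <- seq(floor(min(lt) * bins_per_decade) / bins_per_decade,
                ceiling(max(lt) * bins_per_decade) / bins_per_decade,
                by = 1 / bins_per_decade)
  if (length(breaks) < 2) breaks <- c(breaks - 0.05, breaks + 0.05)
  h <- graphics::hist(lt, breaks = breaks, plot = FALSE)
  out <- list(log10_t = h$mids, sqrt_density = sqrt(h$density))
  if (!is.null(fit)) {
    tt <- 10^h$mids
    # density of log10(t): f(t) * t * ln(10)
    dens <- rowSums(vapply(seq_len(fit$K), function(k)
      fit$weights[k] / fit$taus[k] * exp(-tt / fit$taus[k]), numeric(length(tt))))
    out$fit_sqrt_density <- sqrt(dens * tt * log(10))
  }
  out
}
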