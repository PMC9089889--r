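#' Construct a paired raw/idealization record
#'
#' The universal currency of the pipeline: a raw current trace (pA) paired
#' sample-by-sample with an integer idealization giving the number of open
#' channels at each time point.
#'
#' @param raw numeric vector of current samples (pA)
#' @param label integer vector of open-channel counts, same length as `raw`
#' @param sample_rate sampling rate in Hz
#' @param meta optional named list of provenance metadata
#' @return object of class `paired_record`
#' @export
paired_record <- function(raw, label, sample_rate, meta = list()) {
  raw <- as.numeric(raw)
  label <- as.integer(label)
  if (length(raw) != length(label)) {
    stop("raw and label lengths differ: ", length(raw), " vs ", length(label))
  }
  if (any(label < 0)) stop("label values must be non-negative open counts")
  stopifnot(is.numeric(sample_rate), sample_rate > 0)
  structure(list(raw = raw, label = label,
                 sample_rate = as.numeric(sample_rate), meta = meta),
            class = "paired_record")
}

#' @export
print.paired_record <- function(x, ...) {
  cat("<paired_record> ", length(x$raw), " samples @ ", x$sample_rate, " Hz (",
      format(length(x$raw) / x$sample_rate, digits = 4), " s), levels {",
      paste(sort(unique(x$label)), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
length.paired_record <- function(x) length(x$raw)

#' Simulate a labelled single-channel record from a gating model
#'
#' Draws an exact continuous-time Markov jump chain (Gillespie simulation: at
#' each state the sojourn is exponential with rate `-Q[s,s]`, the destination
#' proportional to the outgoing rates), then snaps the piecewise-constant state
#' path onto the uniform sampling grid. The label row is the open-channel count
#' of the occupied state at each sample; sojourns shorter than one sampling
#' interval are thereby naturally censored, as in a bandwidth-limited
#' recording. The raw row is `baseline + open_count * unitary_current` plus
#' Gaussian noise of sd `noise_sd`, low-pass filtered with a 4-pole Butterworth
#' filter at `filter_cutoff` applied forward only (like an analog amplifier
#' filter). Noise is added before filtering by default (amplifier-referred
#' noise); set `noise_after_filter = TRUE` to add it after. The label row is
#' never filtered.
#'
#' @param model a [gating_model()]
#' @param duration record length in seconds
#' @param seed integer seed; identical seeds give identical records
#' @param noise_after_filter add the noise after the filter instead of before
#' @return a [paired_record()]
#' @examples
#' rec <- sample_trajectory(demo_gating_model(), duration = 1, seed = 1)
#' mean(rec$label)  # empirical open probability, approx 1/3
#' @export
sample_trajectory <- function(model, duration, seed = NULL,
                              noise_after_filter = FALSE) {
  stopifnot(inherits(model, "gating_model"), duration > 0)
  if (any(!is.finite(model$Q))) stop("non-finite rates in Q")
  max_exit <- max(-diag(model$Q))
  if (duration < 10 / max_exit) {
    stop("duration too short to contain events: need >= ",
         format(10 / max_exit), " s for this model")
  }
  n_samp <- duration * model$sample_rate
  if (n_samp > 2^31 - 1) stop("duration x sample_rate exceeds addressable length")
  n_samp <- as.integer(round(n_samp))

  with_seed(seed, {
    pi0 <- equilibrium_distribution(model)
    Q <- model$Q
    n_states <- nrow(Q)
    exit_rate <- -diag(Q)
    jump_prob <- Q / exit_rate
    diag(jump_prob) <- 0

    # Gillespie jump chain until the record is covered
    cap <- max(64L, as.integer(ceiling(duration * max_exit * 1.5)))
    states <- integer(cap); times <- numeric(cap)
    s <- sample.int(n_states, 1, prob = pi0)
    t_now <- 0; k <- 0L
    while (t_now < duration) {
      k <- k + 1L
      if (k > length(states)) {
        states <- c(states, integer(length(states)))
        times <- c(times, numeric(length(times)))
      }
      states[k] <- s; times[k] <- t_now
      t_now <- t_now + rexp(1, exit_rate[s])
      s <- sample.int(n_states, 1, prob = jump_prob[s, ])
    }
    states <- states[seq_len(k)]; times <- times[seq_len(k)]

    grid <- (seq_len(n_samp) - 1) / model$sample_rate
    occ <- states[findInterval(grid, times)]
    label <- model$open_count[occ]

    raw <- model$baseline + label * model$unitary_current
    if (model$noise_sd > 0 && !noise_after_filter) {
      raw <- raw + rnorm(n_samp, 0, model$noise_sd)
    }
    if (!is.null(model$filter_cutoff)) {
      bf <- signal::butter(4, model$filter_cutoff / (model$sample_rate / 2),
                           type = "low")
      raw <- as.numeric(signal::filter(bf, raw))
    }
    if (model$noise_sd > 0 && noise_after_filter) {
      raw <- raw + rnorm(n_samp, 0, model$noise_sd)
    }

    paired_record(raw, label, model$sample_rate,
                  meta = list(source = "hmm_sim", seed = seed,
                              duration = duration))
  })
}
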