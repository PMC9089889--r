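#' Define a Markov gating model for a single ion channel
#'
#' A gating model is a continuous-time Markov chain over conformational states,
#' only some of which conduct. The transition-rate matrix `Q` (1/s) has
#' non-negative off-diagonal rates and rows summing to zero; each state carries
#' an `open_count` (0 for closed states, k for k channels open). Conduction maps
#' linearly to current: a state with `open_count` k produces
#' `baseline + k * unitary_current` picoamperes before noise. Recording-chain
#' realism is modelled by additive Gaussian noise (`noise_sd`, pA) and a 4-pole
#' low-pass Butterworth filter (`filter_cutoff`, Hz) applied to the current row
#' only, emulating a patch-clamp amplifier's analog filter.
#'
#' @param Q square numeric transition-rate matrix (1/s). Off-diagonal entries
#'   must be non-negative and each row must sum to zero (tolerance 1e-9).
#' @param open_count integer vector, one entry per state: number of open
#'   channels in that state. At least one state must be closed (0) and at least
#'   one open (>= 1).
#' @param state_names optional character vector of state identifiers; defaults
#'   to rownames of `Q` or `S1..Sn`.
#' @param unitary_current current step per open channel (pA). Default -5.
#' @param baseline closed-channel current level (pA). Default 0.
#' @param noise_sd standard deviation of the Gaussian noise added to the raw
#'   current (pA). Default 1.
#' @param filter_cutoff low-pass cutoff (Hz) of the 4-pole Butterworth filter;
#'   `NULL` disables filtering. Default 1000.
#' @param sample_rate digitization rate (Hz). Must exceed twice the filter
#'   cutoff. Default 5000.
#' @return An object of class `gating_model`.
#' @examples
#' m <- gating_model(Q = matrix(c(-50, 50, 100, -100), 2, byrow = TRUE),
#'                   open_count = c(0, 1))
#' equilibrium_distribution(m)
#' @export
gating_model <- function(Q, open_count, state_names = NULL,
                         unitary_current = -5, baseline = 0,
                         noise_sd = 1, filter_cutoff = 1000,
                         sample_rate = 5000) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (ncol(Q) != n) stop("Q must be square, got ", n, " x ", ncol(Q))
  if (any(!is.finite(Q))) stop("Q contains non-finite rates")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of Q must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-9)) {
    stop("rows of Q must sum to 0 (max |row sum| = ",
         format(max(abs(rowSums(Q)))), ")")
  }
  open_count <- as.integer(open_count)
  if (length(open_count) != n) stop("open_count must have one entry per state")
  if (any(open_count < 0)) stop("open_count must be non-negative")
  if (!any(open_count == 0) || !any(open_count >= 1)) {
    stop("model needs at least one closed (open_count 0) and one open state")
  }
  if (is.null(state_names)) {
    state_names <- rownames(Q) %||% paste0("S", seq_len(n))
  }
  if (!is.null(filter_cutoff)) {
    stopifnot(filter_cutoff > 0)
    if (sample_rate <= 2 * filter_cutoff) {
      stop("sample_rate must exceed 2 * filter_cutoff (Nyquist)")
    }
  }
  stopifnot(sample_rate > 0, noise_sd >= 0)
  dimnames(Q) <- list(state_names, state_names)
  structure(
    list(state_names = state_names, open_count = open_count, Q = Q,
         unitary_current = unitary_current, baseline = baseline,
         noise_sd = noise_sd, filter_cutoff = filter_cutoff,
         sample_rate = sample_rate),
    class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat("<gating_model> ", length(x$state_names), " states (",
      sum(x$open_count == 0), " closed, ", sum(x$open_count >= 1), " open)\n",
      sep = "")
  cat("  unitary current:", x$unitary_current, "pA; noise sd:", x$noise_sd,
      "pA; filter:", if (is.null(x$filter_cutoff)) "none" else
        paste0(x$filter_cutoff, " Hz"),
      "; sampling:", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Two-state demonstration gating model
#'
#' The default fixture used throughout the package: a single channel gating
#' between one closed and one open state, C <-> O, with opening rate
#' `k_co = 50`/s and closing rate `k_oc = 100`/s (so mean open time 10 ms and
#' equilibrium open probability 1/3), unitary current -5 pA and 1 pA Gaussian
#' noise low-pass filtered at 1 kHz, digitized at 5 kHz. The rate constants are
#' a fixture choice giving visually typical single-channel activity; they are
#' not measurements.
#'
#' @param k_co,k_oc opening / closing rate (1/s)
#' @param ... further arguments passed to [gating_model()]
#' @return a `gating_model`
#' @export
demo_gating_model <- function(k_co = 50, k_oc = 100, ...) {
  Q <- matrix(c(-k_co, k_co, k_oc, -k_oc), 2, 2, byrow = TRUE)
  gating_model(Q, open_count = c(0L, 1L), state_names = c("C", "O"), ...)
}

# Strongly-connected check on the rate graph; returns character vector of
# states unreachable from state 1 in either direction (empty if irreducible).
.disconnected_states <- function(Q, state_names) {
  adj <- Q > 0; diag(adj) <- FALSE
  reach <- function(a) {
    seen <- c(TRUE, rep(FALSE, nrow(a) - 1))
    repeat {
      new <- seen | apply(a[seen, , drop = FALSE], 2, any)
      if (all(new == seen)) break
      seen <- new
    }
    seen
  }
  ok <- reach(adj) & reach(t(adj))
  state_names[!ok]
}

#' Equilibrium occupancy of a gating model
#'
#' Solves pi Q = 0 with sum(pi) = 1 for the stationary distribution of the
#' gating chain. Used as the simulator's validation oracle (the long-run
#' fraction of time in each state) and to draw the initial state.
#'
#' @param model a [gating_model()]
#' @return named numeric probability vector over states
#' @export
equilibrium_distribution <- function(model) {
  stopifnot(inherits(model, "gating_model"))
  Q <- model$Q
  bad <- .disconnected_states(Q, model$state_names)
  if (length(bad)) {
    stop("rate matrix is reducible; states not communicating with the rest: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(Q)
  # pi Q = 0, sum pi = 1  =>  least-squares on the stacked system
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  if (any(pi_hat < -1e-10)) stop("defective rate matrix: negative occupancy")
  pi_hat <- pmax(pi_hat, 0)
  pi_hat <- pi_hat / sum(pi_hat)
  setNames(pi_hat, model$state_names)
}
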