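#' Write a paired record to disk
#'
#' Two on-disk formats are supported. `"csv"` is a plain-text table with header
#' `time_index,current_pA,label` (comma-separated, UTF-8, LF endings). `"arrow"`
#' is a chunked Parquet container (via the arrow package) with one column per
#' signal row and the sample rate stored in the schema metadata; it round-trips
#' the raw row exactly.
#'
#' @param record a [paired_record()]
#' @param path output file path
#' @param format `"csv"` or `"arrow"`
#' @return `path`, invisibly
#' @export
write_record <- function(record, path, format = c("csv", "arrow")) {
  stopifnot(inherits(record, "paired_record"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(time_index = seq_along(record$raw) - 1L,
                     current_pA = record$raw, label = record$label)
    con <- file(path, open = "wb")  # binary mode forces LF endings
    on.exit(close(con))
    writeLines("time_index,current_pA,label", con)
    # CSV is a pure signal table; the sampling rate travels with the caller
    # (read_record requires it). The arrow container embeds it as metadata.
    writeLines(paste(df$time_index,
                     formatC(df$current_pA, format = "g", digits = 17),
                     df$label, sep = ","), con)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for format = \"arrow\"")
    }
    tbl <- arrow::arrow_table(current_pA = record$raw,
                              label = record$label)
    tbl <- tbl$ReplaceSchemaMetadata(list(
      sample_rate = format(record$sample_rate, digits = 17)))
    arrow::write_parquet(tbl, path, chunk_size = 65536L)
  }
  invisible(path)
}

#' Read a paired record from disk
#'
#' @param path file path written by [write_record()] (or any file honouring the
#'   same contract)
#' @param format `"csv"` or `"arrow"`
#' @param sample_rate required for CSV input (the text table does not embed
#'   it); ignored for arrow files, which carry it as metadata.
#' @return a [paired_record()]
#' @export
read_record <- function(path, format = c("csv", "arrow"), sample_rate = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (is.null(sample_rate)) {
      stop("sample_rate must be supplied when reading CSV records")
    }
    first <- readLines(path, n = 1L)
    cols <- strsplit(first, ",", fixed = TRUE)[[1]]
    need <- c("current_pA", "label")
    if (!all(need %in% cols)) {
      stop("CSV header must name the signal columns ",
           paste(need, collapse = " and "), "; got: ", first)
    }
    df <- read.csv(path, header = TRUE)
    if (anyNA(df$current_pA) || anyNA(df$label)) {
      stop("CSV signal columns have unequal lengths: ",
           sum(!is.na(df$current_pA)), " current values vs ",
           sum(!is.na(df$label)), " labels")
    }
    paired_record(df$current_pA, df$label, sample_rate,
                  meta = list(path = path))
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for format = \"arrow\"")
    }
    tbl <- arrow::read_parquet(path, as_data_frame = FALSE)
    md <- tbl$metadata
    if (is.null(md$sample_rate)) stop("arrow container lacks a sample_rate attribute")
    df <- as.data.frame(tbl)
    paired_record(df$current_pA, df$label, as.numeric(md$sample_rate),
                  meta = list(path = path))
  }
}

#' Robust-scale a paired record for GAN training
#'
#' The raw row is centred on its median and divided by its interquartile range
#' (the robust-scaling convention), so outlier current excursions do not
#' dominate the scale. The integer label row is mapped affinely from
#' `[min level, max level]` onto `[-1, 1]` so that both rows live in the tanh
#' output range of the generator; the observed integer levels are recorded in
#' the returned scaler so decoding is exact.
#'
#' @param record a [paired_record()]
#' @return list with `scaled` (2 x L matrix, row 1 raw, row 2 label) and
#'   `scaler` (class `scaler_params`: `center`, `scale`, `label_levels`,
#'   `single_level` flag, `sample_rate`)
#' @seealso [inverse_scale()]
#' @export
robust_scale <- function(record) {
  stopifnot(inherits(record, "paired_record"))
  med <- median(record$raw)
  iqr <- unname(diff(quantile(record$raw, c(0.25, 0.75))))
  if (iqr <= 0) stop("raw row has zero interquartile range; cannot scale")
  levels <- sort(unique(record$label))
  single <- length(levels) == 1L
  if (single) {
    warning("single label level present; label row maps to constant -1")
    lab_scaled <- rep(-1, length(record$label))
  } else {
    lo <- min(levels); hi <- max(levels)
    lab_scaled <- -1 + 2 * (record$label - lo) / (hi - lo)
  }
  scaler <- structure(
    list(center = med, scale = iqr, label_levels = levels,
         single_level = single, sample_rate = record$sample_rate),
    class = "scaler_params")
  scaled <- rbind(raw = (record$raw - med) / iqr, label = lab_scaled)
  list(scaled = scaled, scaler = scaler)
}

#' Invert robust scaling back to physical units
#'
#' @param scaled 2 x L matrix as produced by [robust_scale()]
#' @param scaler the matching `scaler_params`
#' @param snap_labels snap the continuous label row to the nearest recorded
#'   integer level (ties broken toward the lower level); if `FALSE` the
#'   continuous label row is returned as-is in level units.
#' @return a [paired_record()] (when `snap_labels`) or a 2 x L matrix
#' @export
inverse_scale <- function(scaled, scaler, snap_labels = TRUE) {
  stopifnot(inherits(scaler, "scaler_params"), nrow(scaled) == 2)
  raw <- scaled[1, ] * scaler$scale + scaler$center
  levels <- scaler$label_levels
  if (scaler$single_level) {
    lab <- rep(levels, ncol(scaled))
  } else {
    lo <- min(levels); hi <- max(levels)
    lab_cont <- lo + (scaled[2, ] + 1) / 2 * (hi - lo)
    if (!snap_labels) return(rbind(raw = raw, label = lab_cont))
    lab <- snap_to_levels(lab_cont, levels)
  }
  paired_record(raw, lab, scaler$sample_rate)
}

# Nearest recorded level, ties to the lower level.
snap_to_levels <- function(x, levels) {
  levels <- sort(levels)
  d <- abs(outer(x, levels, "-"))
  # which.min returns the first (= lower level) on exact ties
  levels[apply(d, 1, which.min)]
}

#' Slice a scaled record into fixed-width 2-row windows
#'
#' Reshapes the two synchronized signals into a batch of 2 x W "images", the
#' GAN's training and generation unit. Windows are contiguous slices taken
#' every `stride` samples; nothing is ever padded or fabricated. The default
#' width is 1280 samples with non-overlapping stride.
#'
#' @param record a [paired_record()]
#' @param W window length in samples (default 1280)
#' @param stride hop between window starts (default `W`, non-overlapping)
#' @param scaler optionally a precomputed `scaler_params`; by default the
#'   scaler is fit on `record` via [robust_scale()]
#' @return a `window_batch`: list with `data` (N x 2 x W array, scaled),
#'   `window`, `stride`, `scaler`, `source`
#' @export
make_windows <- function(record, W = 1280L, stride = W, scaler = NULL) {
  stopifnot(inherits(record, "paired_record"), stride >= 1)
  L <- length(record$raw)
  if (L < W) stop("record length ", L, " is shorter than window length ", W)
  if (is.null(scaler)) {
    sc <- robust_scale(record)
  } else {
    sc <- list(scaled = robust_scale_with(record, scaler), scaler = scaler)
  }
  scaled <- sc$scaled
  n_win <- (L - W) %/% stride + 1L
  starts <- (seq_len(n_win) - 1L) * stride + 1L
  data <- array(NA_real_, dim = c(n_win, 2L, W))
  for (i in seq_len(n_win)) {
    data[i, , ] <- scaled[, starts[i]:(starts[i] + W - 1L)]
  }
  structure(list(data = data, window = as.integer(W),
                 stride = as.integer(stride), scaler = sc$scaler,
                 source = "real"),
            class = "window_batch")
}

# Apply an existing scaler to a new record (no refitting).
robust_scale_with <- function(record, scaler) {
  stopifnot(inherits(scaler, "scaler_params"))
  raw <- (record$raw - scaler$center) / scaler$scale
  levels <- scaler$label_levels
  if (scaler$single_level) {
    lab <- rep(-1, length(record$label))
  } else {
    lo <- min(levels); hi <- max(levels)
    lab <- -1 + 2 * (record$label - lo) / (hi - lo)
  }
  rbind(raw = raw, label = lab)
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$data)
  cat("<window_batch> ", d[1], " windows of 2 x ", d[3], " (stride ", x$stride,
      "), source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Augment a window batch with faint Gaussian noise
#'
#' Adds Gaussian noise to the raw row only, with standard deviation
#' `noise_fraction` times the peak-to-peak amplitude of the batch's scaled raw
#' row (default 0.1% — invisibly small, but enough to decorrelate repeated
#' presentations of the same window during training). The label row is never
#' touched.
#'
#' @param batch a `window_batch`
#' @param noise_fraction noise sd as a fraction of raw peak-to-peak (default
#'   0.001)
#' @param seed integer seed for reproducibility
#' @return a new `window_batch`
#' @export
augment_windows <- function(batch, noise_fraction = 0.001, seed = NULL) {
  stopifnot(inherits(batch, "window_batch"), noise_fraction >= 0)
  if (noise_fraction == 0) return(batch)
  raw <- batch$data[, 1L, , drop = FALSE]
  ptp <- max(raw) - min(raw)
  with_seed(seed, {
    noise <- array(rnorm(length(raw), 0, noise_fraction * ptp), dim = dim(raw))
    batch$data[, 1L, ] <- batch$data[, 1L, , drop = FALSE] + noise
  })
  batch
}

#' Crop the edges of a generated window
#'
#' Generated windows carry leading and trailing artefacts from the transposed
#' convolutions' edge padding; cropping a fraction of each end before analysis
#' or export removes them. Default 5% per side.
#'
#' @param window a 2 x W matrix, or a `window_batch` (all windows cropped)
#' @param crop_fraction fraction of W removed from each end, in `[0, 0.5)`
#' @return same type as `window`, shortened
#' @export
crop_edges <- function(window, crop_fraction = 0.05) {
  if (crop_fraction < 0 || crop_fraction >= 0.5) {
    stop("crop_fraction must be in [0, 0.5)")
  }
  if (inherits(window, "window_batch")) {
    W <- dim(window$data)[3]
    k <- floor(crop_fraction * W)
    if (k > 0) {
      window$data <- window$data[, , (k + 1):(W - k), drop = FALSE]
      window$window <- as.integer(W - 2 * k)
    }
    return(window)
  }
  stopifnot(is.matrix(window), nrow(window) == 2)
  W <- ncol(window)
  k <- floor(crop_fraction * W)
  if (k == 0) return(window)
  window[, (k + 1):(W - k), drop = FALSE]
}
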