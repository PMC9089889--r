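#' Pool dwell sets from several decoded records
#'
#' Generated data comes as many short records (one per cropped window); their
#' dwell sets are extracted per record — so sojourns truncated at window
#' boundaries stay censored — and pooled for fitting.
#'
#' @param records list of [paired_record()] objects
#' @return a combined `dwell_set`
#' @export
pooled_dwells <- function(records) {
  stopifnot(length(records) >= 1)
  parts <- lapply(records, extract_dwells)
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out, class = c("dwell_set", "data.frame"),
            sample_rate = attr(parts[[1]], "sample_rate"))
}

# Window a list of records with a shared scaler and stack the results.
records_to_windows <- function(records, W, stride = W, scaler) {
  mats <- list()
  for (r in records) {
    if (length(r$raw) < W) next
    b <- make_windows(r, W = W, stride = stride, scaler = scaler)
    mats[[length(mats) + 1]] <- b$data
  }
  if (!length(mats)) stop("no record is long enough for window length ", W)
  data <- do.call(abind_first, mats)
  structure(list(data = data, window = as.integer(W),
                 stride = as.integer(stride), scaler = scaler,
                 source = "generated"),
            class = "window_batch")
}

# rbind for N x 2 x W arrays along the first axis (no abind dependency).
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 1L))
  out <- array(NA_real_, dim = c(total, d[2], d[3]))
  at <- 1L
  for (p in parts) {
    n <- dim(p)[1]
    out[at:(at + n - 1L), , ] <- p
    at <- at + n
  }
  out
}

#' Default pipeline configuration
#'
#' A complete run configuration at demonstration scale: two-state gating model
#' simulated for a few seconds, tiny GAN (W = 64) trained for 200 epochs, and
#' all evaluation stages. Every stochastic stage carries an explicit seed.
#' Override any field via `...` (nested lists are merged).
#'
#' @param out_dir directory the stages write their artifacts into
#' @param ... overrides merged over the defaults, e.g.
#'   `simulate = list(duration = 10)`
#' @return a nested list of class `run_config`
#' @export
default_run_config <- function(out_dir = tempfile("channelgan-run-"), ...) {
  cfg <- list(
    out_dir = out_dir,
    model = list(k_co = 50, k_oc = 100, unitary_current = -5, baseline = 0,
                 noise_sd = 1, filter_cutoff = 1000, sample_rate = 5000),
    simulate = list(duration = 4, seed = 11),
    prepare = list(window = 64L, stride = 64L, holdout_fraction = 0.2),
    gan = list(window = 64L, latent_dim = 16L,
               gen_channels = c(32L, 16L, 8L, 8L),
               disc_channels = c(8L, 16L, 16L),
               batch_size = 32L, epochs = 200L, learning_rate = 1e-3,
               seed = 1L),
    generate = list(n_windows = 64L, seed = 7L, crop_fraction = 0.05),
    evaluate = list(dtw_pairs = 25L, dtw_radius = 1L, seed = 2L),
    kinetics = list(k_max = 4L, seed = 5L),
    embed = list(method = "tsne", window = 32L, seed = 3L),
    clustertest = list(n_permutations = 1000L, seed = 4L))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Configurations round-trip loss-lessly through the YAML text format, so a
#' run is fully described by one plain-text file.
#'
#' @param config a `run_config`
#' @param path YAML file path
#' @return `read_run_config` returns a validated `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- do.call(default_run_config, c(list(out_dir = cfg$out_dir),
                                       cfg[setdiff(names(cfg), "out_dir")]))
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks field types, signs and cross-field constraints; errors name the
#' offending field.
#'
#' @param config a `run_config`
#' @return `config`, invisibly, if valid
#' @export
validate_run_config <- function(config) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field `", field, "`: ", msg, call. = FALSE)
  }
  chk(is.numeric(config$simulate$duration) && config$simulate$duration > 0,
      "simulate.duration", "must be a positive number of seconds")
  chk(config$model$sample_rate > 0, "model.sample_rate", "must be positive")
  chk(is.null(config$model$filter_cutoff) ||
        config$model$sample_rate > 2 * config$model$filter_cutoff,
      "model.filter_cutoff", "sample_rate must exceed twice the cutoff")
  chk(config$prepare$window >= 8 && config$prepare$window %% 8 == 0,
      "prepare.window", "must be a positive multiple of 8")
  chk(config$prepare$stride >= 1, "prepare.stride", "must be >= 1")
  chk(config$generate$crop_fraction >= 0 && config$generate$crop_fraction < 0.5,
      "generate.crop_fraction", "must be in [0, 0.5)")
  chk(config$clustertest$n_permutations >= 1,
      "clustertest.n_permutations", "must be >= 1")
  chk(config$gan$window == config$prepare$window,
      "gan.window", "must equal prepare.window")
  invisible(config)
}

build_model_from_config <- function(mc) {
  if (!is.null(mc$Q)) {
    Q <- do.call(rbind, mc$Q)
    gating_model(Q, open_count = mc$open_count,
                 unitary_current = mc$unitary_current %||% -5,
                 baseline = mc$baseline %||% 0,
                 noise_sd = mc$noise_sd %||% 1,
                 filter_cutoff = mc$filter_cutoff,
                 sample_rate = mc$sample_rate %||% 5000)
  } else {
    demo_gating_model(k_co = mc$k_co, k_oc = mc$k_oc,
                      unitary_current = mc$unitary_current %||% -5,
                      baseline = mc$baseline %||% 0,
                      noise_sd = mc$noise_sd %||% 1,
                      filter_cutoff = mc$filter_cutoff,
                      sample_rate = mc$sample_rate %||% 5000)
  }
}

#' Run the end-to-end pipeline
#'
#' Wires the package's modules into the full workflow:
#' simulate -> prepare -> train -> generate -> evaluate -> kinetics ->
#' embed -> clustertest. Each stage writes its artifact into
#' `config$out_dir` and a log line with the seed used and wall time; stages
#' are idempotent given an identical configuration, and a stage whose
#' upstream artifact is missing errors naming the stage to run first.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [read_run_config()]
#' @param stages subset of the stage names to run, in pipeline order
#' @param verbose print one line per stage (default TRUE)
#' @return named list of the artifact paths written, invisibly
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prepare", "train",
                                    "generate", "evaluate", "kinetics",
                                    "embed", "clustertest"),
                         verbose = TRUE) {
  validate_run_config(config)
  all_stages <- c("simulate", "prepare", "train", "generate", "evaluate",
                  "kinetics", "embed", "clustertest")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    record = file.path(config$out_dir, "rec.csv"),
    windows = file.path(config$out_dir, "windows.rds"),
    checkpoint = file.path(config$out_dir, "checkpoint"),
    train_log = file.path(config$out_dir, "train_log.csv"),
    generated = file.path(config$out_dir, "generated.rds"),
    generated_csv = file.path(config$out_dir, "gen.csv"),
    report = file.path(config$out_dir, "report.json"),
    kinetics = file.path(config$out_dir, "kinetics.json"),
    embedding = file.path(config$out_dir, "embedding.json"),
    clustertest = file.path(config$out_dir, "clustertest.json"))
  log_path <- file.path(config$out_dir, "pipeline.log")
  note <- function(stage, seed, secs) {
    line <- sprintf("%s stage=%s seed=%s wall=%.2fs channelgan=%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                    paste(seed, collapse = ","), secs,
                    as.character(utils::packageVersion("channelgan")))
    cat(line, "\n", file = log_path, append = TRUE)
    if (verbose) message(line)
  }
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("missing upstream artifact ", basename(path),
           "; run the `", stage, "` stage first")
    }
  }
  model <- build_model_from_config(config$model)

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    rec <- sample_trajectory(model, config$simulate$duration,
                             seed = config$simulate$seed)
    write_record(rec, paths$record, format = "csv")
    note("simulate", config$simulate$seed, proc.time()[3] - t0)
  }

  if ("prepare" %in% stages) {
    t0 <- proc.time()[3]
    need(paths$record, "simulate")
    rec <- read_record(paths$record, "csv",
                       sample_rate = config$model$sample_rate)
    batch <- make_windows(rec, W = config$prepare$window,
                          stride = config$prepare$stride)
    n <- dim(batch$data)[1]
    n_hold <- max(2L, floor(config$prepare$holdout_fraction * n))
    hold_idx <- seq(n - n_hold + 1L, n)     # deterministic tail holdout
    holdout <- batch; holdout$data <- batch$data[hold_idx, , , drop = FALSE]
    train <- batch; train$data <- batch$data[-hold_idx, , , drop = FALSE]
    saveRDS(list(train = train, holdout = holdout), paths$windows)
    note("prepare", NA, proc.time()[3] - t0)
  }

  if ("train" %in% stages) {
    t0 <- proc.time()[3]
    need(paths$windows, "prepare")
    w <- readRDS(paths$windows)
    spec <- do.call(gan_spec, config$gan)
    fit <- gan_train(w$train, spec, eval_batch = w$holdout,
                     checkpoint_dir = paths$checkpoint)
    save_gan_checkpoint(list(gen = fit$best_generator %||% fit$gen,
                             disc = fit$disc, spec = spec,
                             scaler = fit$scaler,
                             epoch = fit$best_epoch),
                        file.path(paths$checkpoint, "best"))
    write.csv(fit$log, paths$train_log, row.names = FALSE)
    note("train", config$gan$seed, proc.time()[3] - t0)
  }

  if ("generate" %in% stages) {
    t0 <- proc.time()[3]
    need(file.path(paths$checkpoint, "best"), "train")
    model_ckpt <- load_gan_checkpoint(file.path(paths$checkpoint, "best"))
    batch <- gan_generate(model_ckpt, config$generate$n_windows,
                          seed = config$generate$seed)
    recs <- decode_labels(batch, crop_fraction = config$generate$crop_fraction)
    saveRDS(list(batch = batch, records = recs), paths$generated)
    merged <- paired_record(
      unlist(lapply(recs, `[[`, "raw")),
      unlist(lapply(recs, `[[`, "label")),
      recs[[1]]$sample_rate)
    write_record(merged, paths$generated_csv, format = "csv")
    note("generate", config$generate$seed, proc.time()[3] - t0)
  }

  if ("evaluate" %in% stages) {
    t0 <- proc.time()[3]
    need(paths$windows, "prepare"); need(paths$generated, "generate")
    w <- readRDS(paths$windows)
    gen <- readRDS(paths$generated)
    rep <- evaluate_fidelity(w$holdout, gen$batch,
                             dtw_pairs = config$evaluate$dtw_pairs,
                             dtw_radius = config$evaluate$dtw_radius,
                             seed = config$evaluate$seed)
    jsonlite::write_json(
      list(mmd = rep$mmd, dtw = rep$dtw,
           histogram_distance = rep$histogram_distance,
           parameters = rep$parameters[c("bandwidth", "dtw_pairs",
                                         "dtw_radius", "dtw_cost",
                                         "pairing_seed")]),
      paths$report, auto_unbox = TRUE, digits = NA)
    note("evaluate", config$evaluate$seed, proc.time()[3] - t0)
  }

  if ("kinetics" %in% stages) {
    t0 <- proc.time()[3]
    need(paths$record, "simulate"); need(paths$generated, "generate")
    rec <- read_record(paths$record, "csv",
                       sample_rate = config$model$sample_rate)
    gen <- readRDS(paths$generated)
    out <- list()
    for (side in c("real", "generated")) {
      dw <- if (side == "real") extract_dwells(rec) else
        pooled_dwells(gen$records)
      for (cls in c("open", "closed")) {
        dur <- dwell_durations(dw, cls)
        out[[side]][[cls]] <- if (length(dur) >= 10) {
          f <- select_K(dur, K_max = config$kinetics$k_max,
                        seed = config$kinetics$seed)
          list(K = f$K, tau_ms = f$taus * 1e3, weights = f$weights,
               bic = f$bic, n_dwells = f$n)
        } else list(K = NA, n_dwells = length(dur))
      }
    }
    jsonlite::write_json(out, paths$kinetics, auto_unbox = TRUE, digits = NA)
    note("kinetics", config$kinetics$seed, proc.time()[3] - t0)
  }

  if ("embed" %in% stages) {
    t0 <- proc.time()[3]
    need(paths$windows, "prepare"); need(paths$generated, "generate")
    w <- readRDS(paths$windows)
    gen <- readRDS(paths$generated)
    We <- config$embed$window
    rec <- read_record(paths$record, "csv",
                       sample_rate = config$model$sample_rate)
    real_w <- make_windows(rec, W = We, stride = We,
                           scaler = w$train$scaler)
    gen_w <- records_to_windows(gen$records, W = We, scaler = w$train$scaler)
    emb <- embed_windows(real_w, gen_w, method = config$embed$method,
                         seed = config$embed$seed)
    jsonlite::write_json(
      list(coords = emb$coords, group = as.character(emb$group),
           method = emb$method, seed = emb$seed,
           window_length = emb$window_length),
      paths$embedding, digits = NA)
    note("embed", config$embed$seed, proc.time()[3] - t0)
  }

  if ("clustertest" %in% stages) {
    t0 <- proc.time()[3]
    need(paths$embedding, "embed")
    ej <- jsonlite::read_json(paths$embedding, simplifyVector = TRUE)
    coords <- if (is.matrix(ej$coords)) ej$coords else
      matrix(unlist(ej$coords), ncol = 2, byrow = TRUE)
    emb <- list(coords = coords, group = factor(ej$group))
    ct <- cluster_separation_test(emb,
                                  n_permutations = config$clustertest$n_permutations,
                                  seed = config$clustertest$seed)
    jsonlite::write_json(
      list(statistic = ct$statistic, p_value = ct$p_value,
           n_permutations = ct$n_permutations),
      paths$clustertest, auto_unbox = TRUE, digits = NA)
    note("clustertest", config$clustertest$seed, proc.time()[3] - t0)
  }

  invisible(paths)
}
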