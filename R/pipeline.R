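#' End-to-end pipeline configuration
#'
#' Bundles every stage parameter: the input recording (either a simulator
#' config or paths to a written recording), preprocessing filters, feature
#' windowing, the advance time `delta_t`, the model choice and its
#' configuration, the contiguous train/test split fraction, and a global
#' seed. The split is temporal: the first `split_frac` of the feature stream
#' trains the model, the final portion is held out, so no window of test
#' data leaks into training or into the normalization parameters.
#'
#' @param out_dir directory for stage artifacts.
#' @param sim a [gait_sim_config()] to simulate the input, or `NULL` when
#'   reading from disk.
#' @param input_dir,input_prefix location of an existing recording written by
#'   [write_recording()] (used when `sim` is `NULL`).
#' @param filters a [filter_spec()].
#' @param windows a [window_config()].
#' @param delta_t advance time in seconds (default 0.2).
#' @param model `"lstm"` or `"bpnn"`.
#' @param model_cfg an [lstm_config()] or [bpnn_config()]; `NULL` for
#'   defaults matched to the feature count.
#' @param features `"rrtaf"` (concurrent + time-advanced, 16 columns) or
#'   `"rms"` (concurrent only, 8 columns).
#' @param split_frac training fraction in (0, 1), default 0.8.
#' @param seed global seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            input_dir = NULL, input_prefix = "recording",
                            filters = filter_spec(),
                            windows = window_config(),
                            delta_t = 0.2,
                            model = c("lstm", "bpnn"),
                            model_cfg = NULL,
                            features = c("rrtaf", "rms"),
                            split_frac = 0.8,
                            seed = 1L) {
  model <- match.arg(model)
  features <- match.arg(features)
  if (split_frac <= 0 || split_frac >= 1) {
    stop("`split_frac` must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(sim) && is.null(input_dir)) {
    stop("provide either `sim` or `input_dir`", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, sim = sim, input_dir = input_dir,
         input_prefix = input_prefix, filters = filters, windows = windows,
         delta_t = delta_t, model = model, model_cfg = model_cfg,
         features = features, split_frac = split_frac,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[rrtaf] ", fmt), ...))
}

#' Run the full estimation pipeline
#'
#' simulate (or load) -> preprocess -> featurize -> split -> normalize ->
#' train -> predict -> evaluate. Each stage's artifact is written under
#' `cfg$out_dir` (recording CSVs, feature CSV + sidecar, model JSON,
#' prediction CSV, report JSON) so the pipeline can be resumed from any
#' stage, and every stage logs the parameters it used. Deterministic given
#' the config, including its seeds.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log each stage (default TRUE).
#' @return A list of class `pipeline_report`: `rmse_deg`, `rho`, `n_test`,
#'   `predicted_deg`, `actual_deg`, `model`, `features`, `paths`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  # --- input stage
  if (!is.null(cfg$sim)) {
    pipeline_log(verbose,
                 "simulate: %.1f s, delay %.3f s, seed %d",
                 cfg$sim$duration_s, cfg$sim$delay_s, cfg$sim$seed)
    rec <- simulate_recording(cfg$sim)
    emg <- rec$emg; angle <- rec$angle
    write_recording(emg, angle, cfg$out_dir, "recording",
                    meta = list(delay_s = rec$truth_delay_s,
                                seed = cfg$sim$seed))
  } else {
    pipeline_log(verbose, "load: %s/%s_*", cfg$input_dir, cfg$input_prefix)
    loaded <- read_recording(cfg$input_dir, cfg$input_prefix)
    emg <- loaded$emg; angle <- loaded$angle
  }

  # --- preprocess
  pipeline_log(verbose,
               "preprocess: notch %g Hz (Q %g), band-pass %g-%g Hz order %d, %s",
               cfg$filters$notch_freq, cfg$filters$notch_q,
               cfg$filters$bp_low, cfg$filters$bp_high, cfg$filters$bp_order,
               if (cfg$filters$zero_phase) "zero-phase" else "causal")
  emg_clean <- preprocess_emg(emg, cfg$filters)

  # --- featurize
  ap <- compute_shift_points(cfg$delta_t, angle$fs_angle, emg$fs_emg)
  pipeline_log(verbose,
               "featurize: window %d, delta_t %g s (l = %d, k = %d)",
               cfg$windows$width_N, cfg$delta_t, ap$l, ap$k)
  afs <- build_aligned_features(emg_clean, angle, cfg$windows, ap)
  if (cfg$features == "rms") afs <- concurrent_only(afs)
  feat_path <- file.path(cfg$out_dir, "features.csv")
  write_feature_set(afs, feat_path)

  # --- split + normalize (training statistics only)
  n <- nrow(afs$X)
  n_train <- floor(cfg$split_frac * n)
  if (n_train < 2 || n_train >= n) stop("degenerate train/test split",
                                        call. = FALSE)
  idx_tr <- seq_len(n_train)
  idx_te <- (n_train + 1):n
  norm <- fit_normalization(afs$X[idx_tr, , drop = FALSE], afs$y[idx_tr])
  Xtr <- apply_normalization(afs$X[idx_tr, , drop = FALSE], norm)
  ytr <- apply_normalization(afs$y[idx_tr], norm, target = TRUE)
  Xte <- apply_normalization(afs$X[idx_te, , drop = FALSE], norm)

  # --- train
  n_feat <- ncol(afs$X)
  model_cfg <- cfg$model_cfg
  if (cfg$model == "lstm") {
    if (is.null(model_cfg)) model_cfg <- lstm_config(input_size = n_feat,
                                                     seed = cfg$seed)
    model_cfg$input_size <- as.integer(n_feat)
    pipeline_log(verbose,
                 "train lstm: hidden %d, seq_len %d, %d epochs, seed %d",
                 model_cfg$hidden_size, model_cfg$seq_len, model_cfg$epochs,
                 model_cfg$seed)
    model <- train_lstm(Xtr, ytr, model_cfg)
    yhat_norm <- predict_lstm(model, Xte)
  } else {
    if (is.null(model_cfg)) model_cfg <- bpnn_config(n_input = n_feat,
                                                     seed = cfg$seed)
    model_cfg$n_input <- as.integer(n_feat)
    pipeline_log(verbose,
                 "train bpnn: hidden %d, lr %g, goal %g, max %d epochs, seed %d",
                 model_cfg$n_hidden, model_cfg$learning_rate,
                 model_cfg$goal_mse, model_cfg$max_epochs, model_cfg$seed)
    model <- train_bpnn(Xtr, ytr, model_cfg)
    yhat_norm <- predict_bpnn(model, Xte)
  }
  model_path <- file.path(cfg$out_dir, "model.json")
  save_model(model, model_path, norm = norm)

  # --- predict in degrees + evaluate
  yhat_deg <- invert_normalization(yhat_norm, norm)
  y_actual <- afs$y[idx_te]
  ev <- evaluate_prediction(yhat_deg, y_actual)
  pipeline_log(verbose, "evaluate: RMSE %.4f deg, rho %.4f on %d test steps",
               ev$rmse_deg, ev$rho, length(idx_te))

  pred_path <- file.path(cfg$out_dir, "predictions.csv")
  utils::write.csv(
    data.frame(step = idx_te, actual_deg = y_actual,
               predicted_deg = yhat_deg),
    pred_path, row.names = FALSE
  )
  report <- list(rmse_deg = ev$rmse_deg, rho = ev$rho,
                 n_test = length(idx_te), model = cfg$model,
                 features = cfg$features, delta_t = cfg$delta_t,
                 seed = cfg$seed)
  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)

  structure(
    c(report,
      list(predicted_deg = yhat_deg, actual_deg = y_actual,
           paths = c(features = feat_path, model = model_path,
                     predictions = pred_path, report = report_path))),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> %s using %s: RMSE %.4f deg, rho %.4f (n_test = %d)\n",
    x$model, x$features, x$rmse_deg, x$rho, x$n_test
  ))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: top-level keys `out_dir`, `seed`,
#' `split_frac`, `delta_t`, `model`, `features`, and optional mappings
#' `sim`, `filters`, `windows`, `model_cfg` whose keys are the corresponding
#' constructor arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) if (is.null(args)) NULL else do.call(ctor, args)
  model <- y$model %||% "lstm"
  model_cfg <- NULL
  if (!is.null(y$model_cfg)) {
    model_cfg <- if (model == "lstm") do.call(lstm_config, y$model_cfg)
                 else do.call(bpnn_config, y$model_cfg)
  }
  pipeline_config(
    out_dir = y$out_dir %||% ".",
    sim = build(gait_sim_config, y$sim),
    input_dir = y$input_dir, input_prefix = y$input_prefix %||% "recording",
    filters = build(filter_spec, y$filters) %||% filter_spec(),
    windows = build(window_config, y$windows) %||% window_config(),
    delta_t = y$delta_t %||% 0.2,
    model = model, model_cfg = model_cfg,
    features = y$features %||% "rrtaf",
    split_frac = y$split_frac %||% 0.8,
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
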