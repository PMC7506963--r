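#' Save a trained model (plus normalization) to a single JSON file
#'
#' All weight arrays, the training configuration, the feature-column layout
#' and, when supplied, the min-max normalization parameters go into one
#' human-readable JSON container at full decimal precision, so a checkpoint
#' is self-contained: load it and predict.
#'
#' @param model an `lstm_model` or `bpnn_model`.
#' @param path output file path.
#' @param norm optional [fit_normalization()] result to embed.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, norm = NULL) {
  type <- if (inherits(model, "lstm_model")) "lstm"
          else if (inherits(model, "bpnn_model")) "bpnn"
          else stop("unsupported model class", call. = FALSE)
  payload <- list(
    type = type,
    cfg = unclass(model$cfg),
    weights = lapply(model$weights, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    feature_names = model$feature_names,
    loss = model$loss,
    epochs_run = model$epochs_run,
    norm = if (!is.null(norm)) unclass(norm) else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON checkpoint path.
#' @return A list with `model` (class restored) and `norm`
#'   (`normalization_params` or `NULL`).
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(p$weights, function(el) {
    if (!is.null(el$dim) && length(el$dim)) {
      matrix(el$data, el$dim[1], el$dim[2])
    } else if (length(el$data) == 1) el$data else as.numeric(el$data)
  })
  cfg <- p$cfg
  model <- if (p$type == "lstm") {
    structure(list(weights = weights,
                   cfg = structure(cfg, class = "lstm_config"),
                   feature_names = p$feature_names, loss = p$loss),
              class = "lstm_model")
  } else {
    structure(list(weights = weights,
                   cfg = structure(cfg, class = "bpnn_config"),
                   feature_names = p$feature_names, loss = p$loss,
                   epochs_run = p$epochs_run),
              class = "bpnn_model")
  }
  norm <- NULL
  if (!is.null(p$norm)) {
    norm <- structure(p$norm, class = "normalization_params")
    norm$x_min <- unlist(norm$x_min)
    norm$x_max <- unlist(norm$x_max)
  }
  list(model = model, norm = norm)
}
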