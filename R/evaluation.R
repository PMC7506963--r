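#' Root mean square error between estimated and actual angles
#'
#' `sqrt(mean((estimated - actual)^2))`, in the units of the inputs
#' (degrees for angle series).
#'
#' @param estimated,actual numeric vectors of equal, nonzero length.
#' @return Nonnegative scalar; zero iff the vectors are identical.
#' @export
rmse <- function(estimated, actual) {
  if (length(estimated) != length(actual)) {
    stop("`estimated` and `actual` must have equal length", call. = FALSE)
  }
  if (length(estimated) == 0) stop("empty input", call. = FALSE)
  sqrt(mean((estimated - actual)^2))
}

#' Cross-correlation coefficient between estimated and actual angles
#'
#' The zero-lag Pearson correlation
#' `sum((a - mean(a)) * (e - mean(e))) / sqrt(sum((a - mean(a))^2) * sum((e - mean(e))^2))`,
#' always in `[-1, 1]`.
#'
#' @param estimated,actual numeric vectors of equal length (>= 2), each with
#'   nonzero variance.
#' @return Scalar in `[-1, 1]`.
#' @export
cross_corr_rho <- function(estimated, actual) {
  if (length(estimated) != length(actual)) {
    stop("`estimated` and `actual` must have equal length", call. = FALSE)
  }
  if (length(estimated) < 2) stop("need at least 2 samples", call. = FALSE)
  de <- estimated - mean(estimated)
  da <- actual - mean(actual)
  denom <- sqrt(sum(de^2) * sum(da^2))
  if (denom == 0) {
    stop("zero variance in `estimated` or `actual`; rho undefined",
         call. = FALSE)
  }
  sum(de * da) / denom
}

#' Percent change of a metric relative to a reference method
#'
#' `reduction`: `(reference - new) / reference * 100` (positive when the new
#' method lowers the metric, e.g. RMSE). `increase`:
#' `(new - reference) / reference * 100` (positive when the new method raises
#' it, e.g. the correlation coefficient).
#'
#' @param reference reference-method value (nonzero).
#' @param new new-method value.
#' @param direction `"reduction"` or `"increase"`.
#' @return Percent change (scalar, in %).
#' @export
percent_change <- function(reference, new,
                           direction = c("reduction", "increase")) {
  direction <- match.arg(direction)
  if (any(reference == 0)) stop("zero reference value", call. = FALSE)
  if (direction == "reduction") (reference - new) / reference * 100
  else (new - reference) / reference * 100
}

#' Per-subject evaluation table of the four estimation methods
#'
#' Published per-subject RMSE (degrees) and cross-correlation coefficient
#' values for the four knee-angle estimation methods (BPNN/LSTM, each with
#' the RMS-only and the combined RRTAF feature sets), five subjects walking
#' at 1.0 m/s. Used as the worked example for the cross-method summary
#' arithmetic.
#'
#' @return A long-format data.frame: `subject`, `method`, `metric`, `value`.
#' @export
example_method_table <- function() {
  path <- system.file("extdata", "method_comparison_example.csv",
                      package = "rrtaf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cross-method summary: averages, percent changes, per-subject maxima
#'
#' From a complete long table of per-subject metric values, computes per
#' method and metric the mean and standard deviation, the percent
#' change of each requested method pair computed from the column means, and
#' the per-subject maximum percent change for each pair. RMSE comparisons are
#' reported as reductions, correlation comparisons as increases (see
#' `directions`).
#'
#' @param tbl data.frame with columns `subject`, `method`, `metric`, `value`
#'   and no missing cells.
#' @param comparisons list of `c(reference, new)` method pairs; default: every
#'   ordered pair of distinct methods present.
#' @param directions named character vector mapping each metric to
#'   `"reduction"` or `"increase"`; default
#'   `c(rmse = "reduction", rho = "increase")`.
#' @param round_means optional digit count; when given, column means are
#'   rounded before the percent-change arithmetic (matching tables whose
#'   changes were derived from means printed at fixed precision).
#' @param sd_convention `"population"` (divide by n, the default -- it
#'   reproduces published `+/-` columns of this kind and stays defined for a
#'   single subject) or `"sample"` (divide by n-1).
#' @return A list of class `evaluation_report`: `summary` (method x metric
#'   means and sds), `avg_changes` (percent change of means per pair),
#'   `max_subject_changes` (largest per-subject change per pair, with the
#'   subject attaining it).
#' @export
summarize_methods <- function(tbl, comparisons = NULL,
                              directions = c(rmse = "reduction",
                                             rho = "increase"),
                              round_means = NULL,
                              sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  req <- c("subject", "method", "metric", "value")
  if (!all(req %in% names(tbl))) {
    stop("table needs columns subject, method, metric, value", call. = FALSE)
  }
  if (any(is.na(tbl$value))) stop("missing cells in the table", call. = FALSE)
  methods <- unique(tbl$method)
  metrics <- unique(tbl$metric)
  subjects <- unique(tbl$subject)
  cnt <- table(tbl$method, tbl$metric)
  if (any(cnt != length(subjects))) {
    stop("incomplete table: every method x metric needs one value per subject",
         call. = FALSE)
  }
  if (!all(metrics %in% names(directions))) {
    stop("`directions` must name every metric in the table", call. = FALSE)
  }

  summary_df <- do.call(rbind, lapply(metrics, function(mt) {
    do.call(rbind, lapply(methods, function(me) {
      v <- tbl$value[tbl$method == me & tbl$metric == mt]
      s <- if (length(v) > 1) stats::sd(v) else 0
      if (sd_convention == "population") {
        s <- s * sqrt((length(v) - 1) / length(v))
      }
      data.frame(metric = mt, method = me, mean = mean(v),
                 sd = s, n = length(v))
    }))
  }))

  if (is.null(comparisons)) {
    comparisons <- list()
    for (ref in methods) for (new in setdiff(methods, ref)) {
      comparisons <- c(comparisons, list(c(ref, new)))
    }
  }

  get_col <- function(me, mt) {
    idx <- tbl$method == me & tbl$metric == mt
    v <- tbl$value[idx][order(tbl$subject[idx])]
    v
  }

  avg <- list(); mx <- list()
  for (cmp in comparisons) {
    for (mt in metrics) {
      dir <- directions[[mt]]
      m_ref <- mean(get_col(cmp[1], mt))
      m_new <- mean(get_col(cmp[2], mt))
      if (!is.null(round_means)) {
        m_ref <- round(m_ref, round_means)
        m_new <- round(m_new, round_means)
      }
      avg[[length(avg) + 1]] <- data.frame(
        metric = mt, reference = cmp[1], method = cmp[2], direction = dir,
        percent_change = percent_change(m_ref, m_new, dir)
      )
      per_subj <- percent_change(get_col(cmp[1], mt), get_col(cmp[2], mt), dir)
      best <- which.max(per_subj)
      mx[[length(mx) + 1]] <- data.frame(
        metric = mt, reference = cmp[1], method = cmp[2], direction = dir,
        max_percent_change = per_subj[best],
        subject = sort(subjects)[best]
      )
    }
  }

  structure(
    list(summary = summary_df,
         avg_changes = do.call(rbind, avg),
         max_subject_changes = do.call(rbind, mx)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\nMethod summaries (mean +/- sd):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s %-12s %.4f +/- %.4f (n = %d)\n",
                s$metric[i], s$method[i], s$mean[i], s$sd[i], s$n[i]))
  }
  cat("Average percent changes:\n")
  a <- x$avg_changes
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-6s %s -> %s: %s %.2f%%\n", a$metric[i], a$reference[i],
                a$method[i], a$direction[i], a$percent_change[i]))
  }
  invisible(x)
}

#' Evaluate a prediction against the measured angle
#'
#' Convenience wrapper computing both criteria at once.
#'
#' @param estimated,actual angle vectors in degrees.
#' @return A list with `rmse_deg` and `rho`.
#' @export
evaluate_prediction <- function(estimated, actual) {
  list(rmse_deg = rmse(estimated, actual),
       rho = cross_corr_rho(estimated, actual))
}
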