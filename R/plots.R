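#' Plot the error CDF of one or more evaluation arms
#'
#' @param errors tibble with columns `error_mm` and optionally `arm`.
#' @return A ggplot object (cumulative fraction of landmark instances
#'   within each error threshold).
#' @export
pm_plot_error_cdf <- function(errors) {
  if (!"arm" %in% names(errors)) errors$arm <- "pipeline"
  ok <- !is.na(errors$error_mm)
  ggplot2::ggplot(errors[ok, ],
                  ggplot2::aes(x = .data$error_mm, colour = .data$arm)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(x = "localization error (mm)",
                  y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pm_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$threshold_mm, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$median_mm, linetype = 2) +
    ggplot2::labs(x = "error threshold (mm)", y = "cumulative fraction",
                  title = sprintf("median %.2f mm", object$median_mm)) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param history tibble with columns `epoch`, `train_loss`, `val_loss`
#'   (from the `pm_train_*` fits).
#' @return A ggplot object.
#' @export
pm_plot_history <- function(history) {
  long <- rbind(
    data.frame(epoch = history$epoch, loss = history$train_loss, set = "train"),
    data.frame(epoch = history$epoch, loss = history$val_loss, set = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export an evaluation report as long-format CSV and JSON
#'
#' Writes `<stem>.csv` (columns metric, group, value), `<stem>_cdf.csv`
#' (two columns: threshold, fraction) and `<stem>.json`.
#'
#' @param report a `pm_eval_report`.
#' @param stem output path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
pm_export_report <- function(report, stem) {
  long <- rbind(
    data.frame(metric = "median_mm", group = "overall", value = report$median_mm),
    data.frame(metric = "subject_mean_mm", group = "overall",
               value = report$subject_mean_mm),
    data.frame(metric = "subject_ci_lo_mm", group = "overall",
               value = report$subject_ci_mm[1]),
    data.frame(metric = "subject_ci_hi_mm", group = "overall",
               value = report$subject_ci_mm[2]))
  if (!is.null(report$per_landmark)) {
    long <- rbind(long, data.frame(metric = "median_mm",
                                   group = report$per_landmark$landmark,
                                   value = report$per_landmark$median_mm))
  }
  p_csv <- paste0(stem, ".csv")
  p_cdf <- paste0(stem, "_cdf.csv")
  p_json <- paste0(stem, ".json")
  utils::write.csv(long, p_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(report$cdf), p_cdf, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(report), p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_csv, p_cdf, p_json))
}
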