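# broom-style tidiers and ggplot2 autoplot methods for the result types

#' @export
tidy.deposit_classifier <- function(x, ...) x$history

#' @export
glance.deposit_classifier <- function(x, ...) {
  tibble(backbone = x$config$backbone, n_train = x$n_train,
         epochs = nrow(x$history), final_loss = tail(x$history$loss, 1),
         seed = x$seed)
}

#' @export
tidy.accuracy_report <- function(x, ...) x$scores

#' @export
glance.accuracy_report <- function(x, ...) {
  tibble(mean_f1 = x$mean_f1,
         n_gt = sum(x$confusion[, c("urine", "feces")]),
         n_false_alarms = sum(x$confusion[c("urine", "feces"), "background"]),
         n_miss = sum(x$confusion["miss", ]))
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(pred = rep(rownames(m), times = ncol(m)),
         gt = rep(colnames(m), each = nrow(m)),
         n = as.vector(m))
}

#' @export
tidy.stage_summary <- function(x, ...) x$windows

#' @export
glance.stage_summary <- function(x, ...) {
  tidyr::pivot_wider(x$active, names_from = "label", values_from = "active",
                     names_prefix = "active_")
}

#' @export
tidy.match_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$gt[, c("label", "status")], role = "ground_truth"),
    tibble(label = x$det$label, status = x$det$role, role = "detection"))
}

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: a thermal frame
#' (`thermal_video`), the confusion matrix, the per-class accuracy scores
#' and the training-loss history.
#'
#' @param object The object to plot.
#' @param frame 0-based frame index (for `thermal_video`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name thermark-autoplot
NULL

#' @rdname thermark-autoplot
#' @export
autoplot.thermal_video <- function(object, frame = 0, ...) {
  fr <- frame_at(object, frame)
  df <- tidyr::expand_grid(y = seq_len(nrow(fr)) - 1L,
                           x = seq_len(ncol(fr)) - 1L)
  df$temp <- as.vector(t(fr))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$temp)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "°C") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d (t = %.1f s)", frame,
                                  object$timestamps[frame + 1]),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname thermark-autoplot
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  df$pred <- factor(df$pred, levels = rev(rownames(object)))
  df$gt <- factor(df$gt, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$gt, .data$pred, fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "ground truth", y = "predicted") +
    ggplot2::theme_minimal()
}

#' @rdname thermark-autoplot
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scores[, c("class", "precision", "recall", "f1")],
                            -"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$mean_f1, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = NULL,
                  subtitle = sprintf("mean F1 = %.2f", object$mean_f1)) +
    ggplot2::theme_minimal()
}

#' @rdname thermark-autoplot
#' @export
autoplot.deposit_classifier <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(seq_along(.data$loss), .data$loss,
                               color = factor(.data$round))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss", color = "round") +
    ggplot2::theme_minimal()
}

#' Per-minute deposition plot
#'
#' Line plot of the per-minute event rate (or area) per label and stage.
#'
#' @param minutes Tibble from [per_minute_series()].
#' @param measure `"rate"` or `"area"`.
#' @return A ggplot object.
#' @export
plot_minute_series <- function(minutes, measure = c("rate", "area")) {
  measure <- match.arg(measure)
  ggplot2::ggplot(minutes,
                  ggplot2::aes(.data$minute, .data[[measure]],
                               color = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = "minute of stage",
                  y = if (measure == "rate") "events / min" else "cm² / min") +
    ggplot2::theme_minimal()
}
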