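#' Plot a connectivity volume
#'
#' Raster plot of a 2-D volume (or one slice of a 3-D volume), with
#' undefined voxels left blank.
#'
#' @param object an [fc_volume()].
#' @param slice slice index along the third axis for 3-D volumes.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fc_volume <- function(object, slice = 1, ...) {
  df <- tidy(object)
  if ("z" %in% names(df)) df <- dplyr::filter(df, .data$z == slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = object$metric, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phantom's spatial components
#'
#' @param object a `bold_phantom`.
#' @param ... unused.
#' @return a ggplot object showing the ground-truth component labels.
#' @export
autoplot.bold_phantom <- function(object, ...) {
  labels <- Reduce(`+`, lapply(seq_along(object$masks),
                               function(i) i * (object$masks[[i]] & TRUE)))
  d <- dim(labels)
  df <- tibble::tibble(
    x = rep(seq_len(d[1L]), d[2L]),
    y = rep(seq_len(d[2L]), each = d[1L]),
    component = factor(as.vector(labels))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$component)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "component") +
    ggplot2::theme_minimal()
}

#' Plot a time course with its detected onsets
#'
#' @param tc time course (tibble with `time_s` and `value`, or numeric
#'   vector).
#' @param onsets detection tibble from [detect_onsets()] (or 0-based
#'   indices).
#' @param tr repetition time in seconds, for bare-vector input.
#' @return a ggplot object: the BOLD signal with vertical onset markers.
#' @export
plot_detection <- function(tc, onsets, tr = NULL) {
  v <- tc_values(tc)
  tr <- tc_tr(tc, tr)
  idx <- onset_indices(onsets)
  df <- tibble::tibble(time_s = (seq_along(v) - 1) * tr, value = v)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = idx * tr, colour = "red",
                        linetype = "dashed", alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = "BOLD signal") +
    ggplot2::theme_minimal()
}

#' Plot detector benchmark results
#'
#' @param object a `detector_benchmark`.
#' @param ... unused.
#' @return a ggplot object: run-level sensitivity and specificity per
#'   detector.
#' @export
autoplot.detector_benchmark <- function(object, ...) {
  df <- tidyr::pivot_longer(object$runs, c("sensitivity", "specificity"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$detector, .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
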