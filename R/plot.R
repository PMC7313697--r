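# ggplot2 views of tracked results.

#' Plot joint-angle time series
#'
#' One facet per joint; optionally overlays a ground-truth series.
#'
#' @param angles Angles tibble (`frame_index`, `joint_name`, `theta_deg`).
#' @param truth Optional ground-truth tibble with the same columns.
#' @return A ggplot object.
#' @export
plot_angles <- function(angles, truth = NULL) {
  p <- ggplot2::ggplot(angles,
                       ggplot2::aes(x = .data$frame_index,
                                    y = .data$theta_deg)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~joint_name) +
    ggplot2::labs(x = "frame", y = "angle (deg)")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(data = truth, linetype = "dashed",
                                color = "grey40")
  }
  p
}

#' Plot marker trajectories in the image plane
#'
#' @param detections Detections tibble.
#' @return A ggplot object with the y axis flipped to image orientation.
#' @export
plot_tracks <- function(detections) {
  ggplot2::ggplot(detections,
                  ggplot2::aes(x = .data$u_px, y = .data$v_px,
                               color = .data$status)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$marker_id),
                       color = "grey70") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~marker_id) +
    ggplot2::labs(x = "u (px)", y = "v (px)")
}

#' Autoplot method for tracked results
#' @param object `mm_result` from [mm_track()].
#' @param what `"angles"` or `"tracks"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_result <- function(object, what = c("angles", "tracks"), ...) {
  what <- match.arg(what)
  if (what == "angles") plot_angles(object$angles)
  else plot_tracks(object$detections)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
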