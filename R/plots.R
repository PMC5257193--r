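#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted normative trajectory
#'
#' The normative curve (fixed-effects prediction at baseline covariates)
#' over the training age range, optionally with the training observations.
#'
#' @param object A `normative_fit`.
#' @param data Optional long cohort tibble to overlay the feature's
#'   observations, colored by group.
#' @param n_grid Grid resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normative_fit <- function(object, data = NULL, n_grid = 200, ...) {
  grid <- tibble::tibble(
    age = seq(object$age_range[1], object$age_range[2], length.out = n_grid))
  grid$value <- predict_mean(object, grid$age)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$age, y = .data$value))
  if (!is.null(data)) {
    if (all(c("roi", "parameter") %in% names(data)) && !is.na(object$feature)) {
      data <- data[paste(data$roi, data$parameter, sep = ".") == object$feature, ,
                   drop = FALSE]
    }
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data$age, y = .data$value, color = .data$group),
      alpha = 0.5, size = 1)
  }
  p + ggplot2::geom_line(linewidth = 1, color = "#2c5f8a") +
    ggplot2::labs(x = "Age (years)", y = object$feature,
                  title = "Normative developmental trajectory") +
    ggplot2::theme_minimal()
}

#' Plot deviation-score distributions by group
#'
#' Overlaid histograms of subject-mean Mahalanobis distances for the ASD
#' and TDC groups -- the distributional view that the Bhattacharyya
#' coefficient summarizes.
#'
#' @param object A `deviation_result`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deviation_result <- function(object, bins = 20, ...) {
  ggplot2::ggplot(object$subjects,
                  ggplot2::aes(x = .data$dm, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::scale_fill_manual(values = c(ASD = "#c0392b", TDC = "#2980b9")) +
    ggplot2::labs(x = "Subject-mean Mahalanobis distance", y = "Subjects",
                  fill = NULL,
                  title = "Deviation from the normative reference") +
    ggplot2::theme_minimal()
}

#' Plot per-preset group separation of a pipeline run
#'
#' Subject-mean distance distributions for every feature preset, faceted,
#' with free x scales (distances grow with feature dimension).
#'
#' @param object A `deviation_pipeline`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deviation_pipeline <- function(object, bins = 20, ...) {
  d <- dplyr::bind_rows(purrr::imap(object$deviations, function(dv, nm) {
    out <- dv$subjects
    out$preset <- nm
    out
  }))
  d$preset <- factor(d$preset, levels = names(object$deviations))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dm, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~preset, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(ASD = "#c0392b", TDC = "#2980b9")) +
    ggplot2::labs(x = "Subject-mean Mahalanobis distance", y = "Subjects",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
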