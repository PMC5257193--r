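#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normative fit into a coefficient tibble
#'
#' @param x A `normative_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model term.
#' @export
tidy.normative_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("spline_", seq_along(x$theta)),
             if (x$use_coil) "coil" else NULL,
             if (x$use_tmi) "tmi" else NULL),
    estimate = c(x$theta,
                 if (x$use_coil) x$beta_coil else NULL,
                 if (x$use_tmi) x$beta_tmi else NULL))
}

#' One-row summary of a normative fit
#'
#' @param x A `normative_fit`.
#' @param ... Unused.
#' @return One-row tibble: feature, smoothing parameter, effective degrees
#'   of freedom, variance components and sample sizes.
#' @export
glance.normative_fit <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, lambda = x$lambda, edf = x$edf,
    sigma_u = x$sigma_u, sigma_eps = x$sigma_eps,
    sigma_resid = x$sigma_resid, rho = x$rho,
    n_scans = x$n_scans, n_subjects = x$n_subjects,
    age_min = x$age_range[1], age_max = x$age_range[2],
    iterations = x$iterations)
}

#' Tidy a deviation result into subject-level rows
#'
#' @param x A `deviation_result`.
#' @param ... Unused.
#' @return Tibble: subject_id, group, n_scans, dm, loo.
#' @export
tidy.deviation_result <- function(x, ...) x$subjects

#' Group-level summary of a deviation result
#'
#' @param x A `deviation_result`.
#' @param ... Unused.
#' @return One row per group: n, mean/SD of subject-mean distance.
#' @export
glance.deviation_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$subjects, .data$group),
                   n = dplyr::n(), mean_dm = mean(.data$dm),
                   sd_dm = stats::sd(.data$dm), .groups = "drop")
}

#' Tidy a pipeline into its per-preset summary table
#'
#' @param x A `deviation_pipeline`.
#' @param ... Unused.
#' @return The per-preset summary tibble.
#' @export
tidy.deviation_pipeline <- function(x, ...) x$summary
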