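#' Assemble the scan-by-feature marginal residual matrix
#'
#' Entry (scan, j) is the marginal residual of that scan's j-th feature
#' against its normative fit; columns follow the feature-spec order, rows
#' the deterministic cohort order.
#'
#' @param cohort Long cohort tibble.
#' @param fits Named list of `normative_fit` objects (one per feature).
#' @param spec A [feature_spec()].
#' @param groups Optional group filter (e.g. `"ASD"`); `NULL` keeps all.
#' @return List of class `residual_matrix`: `info` (scan metadata tibble)
#'   and `R` (residual matrix).
#' @export
assemble_residual_matrix <- function(cohort, fits, spec = default_feature_spec(),
                                     groups = NULL) {
  missing_fit <- setdiff(spec$feature, names(fits))
  if (length(missing_fit) > 0) {
    stop("no normative fit for feature(s): ",
         paste(utils::head(missing_fit, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(groups)) {
    cohort <- cohort[cohort$group %in% groups, , drop = FALSE]
  }
  sc <- cohort_scans(cohort, spec)
  R <- vapply(spec$feature, function(f) {
    sc$info$value <- sc$Y[, f]
    sc$info$value - predict_mean(fits[[f]], sc$info$age, sc$info$coil,
                                 sc$info$tmi)
  }, numeric(nrow(sc$info)))
  if (is.null(dim(R))) R <- matrix(R, nrow = 1, dimnames = list(NULL, spec$feature))
  structure(list(info = sc$info, R = R), class = "residual_matrix")
}

# residual matrices whose entries are all numerically zero correspond to a
# cohort lying exactly on the normative curves; deviations are zero by
# definition and no covariance can (or need) be estimated
all_zero_residuals <- function(R) {
  max(abs(R)) < 1e-10
}

# score one group's scans against given fits + covariance; returns per-scan
# and per-subject tibbles plus per-(subject, feature) standard scores
score_rows <- function(info, R, fits, cov, spec, loo = FALSE) {
  dm <- if (is.null(cov)) rep(0, nrow(R)) else mahalanobis_distance(R, cov)
  scans <- tibble::tibble(
    subject_id = info$subject_id, group = info$group,
    scan_index = info$scan_index, age = info$age, dm = dm, loo = loo)
  subjects <- dplyr::summarise(
    dplyr::group_by(scans, .data$subject_id, .data$group),
    n_scans = dplyr::n(), dm = subject_mean_distance(.data$dm),
    .groups = "drop")
  subjects$loo <- loo

  sig <- vapply(spec$feature, function(f) fits[[f]]$sigma_resid, numeric(1))
  Z <- R / matrix(pmax(sig, 1e-300), nrow(R), ncol(R), byrow = TRUE)
  zdf <- tibble::as_tibble(Z)
  zdf$subject_id <- info$subject_id
  zdf$group <- info$group
  long <- tidyr::pivot_longer(zdf, cols = dplyr::all_of(spec$feature),
                              names_to = "feature", values_to = "z")
  scores <- dplyr::summarise(
    dplyr::group_by(long, .data$subject_id, .data$group, .data$feature),
    score_signed = mean(.data$z), .groups = "drop")
  scores$score_abs <- abs(scores$score_signed)
  scores$loo <- loo
  list(scans = scans, subjects = subjects, scores = scores)
}

#' Score a group's deviations against fixed normative models
#'
#' Computes per-scan Mahalanobis distances, subject-mean distances and
#' univariate standard scores for every subject of `group`, using fits and
#' a covariance estimated on the TDC reference (scan residual / sigma for
#' the standard scores; signed subject aggregates and their absolute
#' values are both returned).
#'
#' @param cohort Long cohort tibble.
#' @param fits Named list of `normative_fit` objects.
#' @param cov A `covariance_model` estimated on TDC residuals (or `NULL`
#'   for a fully degenerate zero-residual cohort).
#' @param spec A [feature_spec()].
#' @param group Group to score (`"ASD"` or `"TDC"`).
#' @return List with `scans`, `subjects`, `scores` tibbles.
#' @export
group_deviations <- function(cohort, fits, cov, spec = default_feature_spec(),
                             group = "ASD") {
  rm <- assemble_residual_matrix(cohort, fits, spec, groups = group)
  if (is.null(cov) && !all_zero_residuals(rm$R)) {
    stop("a covariance model is required for non-degenerate residuals",
         call. = FALSE)
  }
  score_rows(rm$info, rm$R, fits, cov, spec, loo = FALSE)
}

#' @rdname group_deviations
#' @export
asd_deviations <- function(cohort, fits, cov, spec = default_feature_spec()) {
  group_deviations(cohort, fits, cov, spec, group = "ASD")
}

#' Leave-one-out deviations for the reference group
#'
#' For each TDC subject, all feature models and the residual covariance
#' are re-estimated on the remaining TDC subjects (knot locations,
#' smoothing parameter and variance ratio held at the full-fit values),
#' and the held-out subject's scans are scored against those refits --
#' avoiding self-reference bias in the control distances.
#'
#' @param cohort Long cohort tibble.
#' @param spec A [feature_spec()].
#' @param smoother A [smoother_config()].
#' @param cov_estimator,cov_gamma Covariance estimator settings as in
#'   [estimate_covariance()].
#' @param fits Optional pre-computed full-TDC fits (from
#'   [fit_normative_set()]); fitted internally when `NULL`.
#' @return List with `scans`, `subjects`, `scores` tibbles (one subject
#'   entry per TDC subject) and the full-fit list as `fits`.
#' @export
loo_tdc_deviations <- function(cohort, spec = default_feature_spec(),
                               smoother = smoother_config(),
                               cov_estimator = "shrinkage", cov_gamma = NULL,
                               fits = NULL) {
  tdc <- cohort[cohort$group == "TDC", , drop = FALSE]
  subjects <- unique(tdc$subject_id)
  if (length(subjects) < smoother$min_subjects + 1) {
    stop("insufficient TDC subjects for leave-one-out scoring", call. = FALSE)
  }
  if (is.null(fits)) fits <- fit_normative_set(tdc, spec, smoother)

  sc <- cohort_scans(tdc, spec)
  info <- sc$info
  # per-feature per-scan training frames reused across held-out subjects
  frames <- lapply(spec$feature, function(f) {
    tibble::tibble(subject_id = info$subject_id, age = info$age,
                   coil = info$coil, tmi = info$tmi, value = sc$Y[, f])
  })
  names(frames) <- spec$feature

  out <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    held <- info$subject_id == s
    E_rest <- matrix(0, sum(!held), nrow(spec))
    e_held <- matrix(0, sum(held), nrow(spec))
    sig <- numeric(nrow(spec))
    for (j in seq_len(nrow(spec))) {
      f <- spec$feature[j]
      rf <- pls_refit(fits[[f]], frames[[f]][!held, , drop = FALSE],
                      frames[[f]][held, , drop = FALSE])
      E_rest[, j] <- rf$resid_train
      e_held[, j] <- rf$resid_eval
      sig[j] <- rf$sigma_resid
    }
    colnames(e_held) <- spec$feature
    degenerate <- all_zero_residuals(E_rest) && all_zero_residuals(e_held)
    if (degenerate) {
      dm <- rep(0, sum(held))
    } else {
      cov_k <- estimate_covariance(E_rest, estimator = cov_estimator,
                                   gamma = cov_gamma)
      dm <- mahalanobis_distance(e_held, cov_k)
    }
    z <- e_held / matrix(pmax(sig, 1e-300), sum(held), nrow(spec), byrow = TRUE)
    out[[k]] <- list(
      scans = tibble::tibble(subject_id = s, group = "TDC",
                             scan_index = info$scan_index[held],
                             age = info$age[held], dm = dm, loo = TRUE),
      scores = tibble::tibble(subject_id = s, group = "TDC",
                              feature = spec$feature,
                              score_signed = colMeans(z),
                              score_abs = abs(colMeans(z)), loo = TRUE))
  }
  scans <- dplyr::bind_rows(purrr::map(out, "scans"))
  subjects_tbl <- dplyr::summarise(
    dplyr::group_by(scans, .data$subject_id, .data$group),
    n_scans = dplyr::n(), dm = subject_mean_distance(.data$dm),
    .groups = "drop")
  subjects_tbl$loo <- TRUE
  list(scans = scans, subjects = subjects_tbl,
       scores = dplyr::bind_rows(purrr::map(out, "scores")), fits = fits)
}

#' Univariate standard scores for one subject and feature
#'
#' Per-scan signed score = marginal residual divided by the fit's residual
#' SD; the subject aggregate is the mean over scans, returned both signed
#' and in absolute value (the absolute value is what enters the
#' distribution comparisons).
#'
#' @param fit A `normative_fit`.
#' @param data The subject's scans (long cohort rows for the fit's feature
#'   or a per-scan frame with `age`, `coil`, `tmi`, `value`).
#' @return List: `per_scan` (signed scores), `aggregate_signed`,
#'   `aggregate_abs`.
#' @export
standard_scores <- function(fit, data) {
  if (fit$sigma_resid < 1e-12) {
    stop("degenerate fit: residual SD is (numerically) zero", call. = FALSE)
  }
  z <- marginal_residuals(fit, data) / fit$sigma_resid
  list(per_scan = z, aggregate_signed = mean(z), aggregate_abs = abs(mean(z)))
}

#' Score a whole cohort's deviations from the normative reference
#'
#' The end-to-end deviation stage: fits normative trajectories on the TDC
#' scans, estimates the TDC residual covariance, scores every ASD subject
#' against the reference, and scores every TDC subject by leave-one-out.
#'
#' @param cohort Long cohort tibble.
#' @param spec A [feature_spec()].
#' @param smoother A [smoother_config()].
#' @param cov_estimator,cov_gamma Covariance settings.
#' @param loo Score TDC subjects by leave-one-out (`TRUE`, default) or
#'   in-sample against the full-TDC fits.
#' @return Object of class `deviation_result` with tibbles `scans`,
#'   `subjects`, `scores`, plus `cov` and `fits`.
#' @export
score_deviations <- function(cohort, spec = default_feature_spec(),
                             smoother = smoother_config(),
                             cov_estimator = "shrinkage", cov_gamma = NULL,
                             loo = TRUE) {
  tdc <- cohort[cohort$group == "TDC", , drop = FALSE]
  fits <- fit_normative_set(tdc, spec, smoother)
  rm_tdc <- assemble_residual_matrix(cohort, fits, spec, groups = "TDC")
  cov <- if (all_zero_residuals(rm_tdc$R)) NULL else {
    estimate_covariance(rm_tdc$R, estimator = cov_estimator, gamma = cov_gamma)
  }

  parts <- list()
  if (any(cohort$group == "ASD")) {
    parts$asd <- group_deviations(cohort, fits, cov, spec, group = "ASD")
  }
  if (loo) {
    tl <- loo_tdc_deviations(cohort, spec, smoother,
                             cov_estimator = cov_estimator,
                             cov_gamma = cov_gamma, fits = fits)
    parts$tdc <- tl[c("scans", "subjects", "scores")]
  } else {
    parts$tdc <- group_deviations(cohort, fits, cov, spec, group = "TDC")
  }

  structure(list(
    scans = dplyr::bind_rows(purrr::map(parts, "scans")),
    subjects = dplyr::bind_rows(purrr::map(parts, "subjects")),
    scores = dplyr::bind_rows(purrr::map(parts, "scores")),
    cov = cov, fits = fits, spec = spec, loo = loo),
    class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  g <- dplyr::summarise(dplyr::group_by(x$subjects, .data$group),
                        n = dplyr::n(), mean_dm = mean(.data$dm),
                        sd_dm = stats::sd(.data$dm), .groups = "drop")
  cat("Deviation result (", nrow(x$spec), " features, TDC scoring: ",
      if (x$loo) "leave-one-out" else "in-sample", ")\n", sep = "")
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}
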