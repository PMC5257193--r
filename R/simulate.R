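#' Paper-style visit structure
#'
#' The accelerated-longitudinal design of record: 57 participants with four
#' scans (42 ASD, 15 TDC), 32 with three (18/14), 37 with two (18/19) and 23
#' with one (14/9) -- 92 ASD subjects contributing 272 scans and 57 TDC
#' subjects contributing 149 scans, 421 scans in total.
#'
#' @return Tibble with columns `n_subjects`, `n_scans`, `group`.
#' @export
default_visit_structure <- function() {
  tibble::tibble(
    n_subjects = c(42L, 18L, 18L, 14L, 15L, 14L, 19L, 9L),
    n_scans    = c(4L, 3L, 2L, 1L, 4L, 3L, 2L, 1L),
    group      = rep(c("ASD", "TDC"), c(4L, 4L)))
}

# deterministic per-feature curve parameters for f(age) = a + b * exp(-age / c).
# FA rises toward an asymptote; diffusivities fall. Small ROI-indexed offsets
# keep features distinct without introducing randomness.
default_trajectories <- function(spec) {
  base <- list(
    FA = c(a = 0.55, b = -0.25, c = 5.0),
    MD = c(a = 0.75, b = 0.35, c = 4.0),
    AD = c(a = 1.15, b = 0.30, c = 4.0),
    RD = c(a = 0.55, b = 0.40, c = 4.5))
  roi_idx <- match(spec$roi, unique(spec$roi)) - 1L
  p <- base[spec$parameter]
  tibble::tibble(
    feature = spec$feature,
    a = vapply(p, `[[`, 0, "a") + 0.008 * (roi_idx %% 5L - 2L),
    b = vapply(p, `[[`, 0, "b") * (1 + 0.05 * (roi_idx %% 3L - 1L)),
    c = vapply(p, `[[`, 0, "c") * (1 + 0.08 * (roi_idx %% 4L - 1.5)))
}

default_param_scale <- function(what = c("resid", "subject")) {
  what <- match.arg(what)
  r <- c(FA = 0.020, MD = 0.022, AD = 0.028, RD = 0.024)
  if (what == "resid") r else 0.6 * r
}

# within-ROI cross-parameter residual correlation (order FA, MD, AD, RD):
# FA anticorrelated with MD and RD, weakly positive with AD; diffusivities
# mutually positive. Positive definite (min eigenvalue ~ 0.066).
default_param_cor <- function() {
  R <- diag(4)
  dimnames(R) <- list(dti_parameters(), dti_parameters())
  R["FA", "MD"] <- R["MD", "FA"] <- -0.4
  R["FA", "AD"] <- R["AD", "FA"] <- 0.2
  R["FA", "RD"] <- R["RD", "FA"] <- -0.5
  R["MD", "AD"] <- R["AD", "MD"] <- 0.6
  R["MD", "RD"] <- R["RD", "MD"] <- 0.6
  R["AD", "RD"] <- R["RD", "AD"] <- 0.6
  R
}

#' Configure the synthetic-cohort generator
#'
#' Defines an accelerated longitudinal study: per-group blocks of subjects
#' with fixed scan counts, uniform baseline ages, Gamma-distributed
#' inter-scan intervals, exponential-approach normative trajectories per
#' feature, subject random intercepts, a block-correlated within-scan
#' residual covariance, additive nuisance-covariate effects (head coil,
#' total motion index), and a configurable ASD deviation: a mean shift of
#' `asd_shift` residual SDs (signed per parameter) plus variance inflation
#' `asd_scale`.
#'
#' @param spec [feature_spec()] defining the simulated features.
#' @param visit_structure Tibble (`n_subjects`, `n_scans`, `group`);
#'   defaults to [default_visit_structure()].
#' @param age_range Baseline-age range in years (uniform).
#' @param interval_mean,interval_sd Mean/SD (years) of the Gamma inter-scan
#'   interval.
#' @param trajectory Tibble (`feature`, `a`, `b`, `c`) for
#'   `f(age) = a + b * exp(-age / c)`; defaults derived from the parameter.
#' @param resid_sd,subject_sd Named per-parameter SDs (expanded per
#'   feature) of the within-scan residual and the subject random intercept.
#' @param param_cor 4x4 within-ROI cross-parameter correlation.
#' @param roi_cor Cross-ROI correlation (equicorrelation, Kronecker with
#'   `param_cor`).
#' @param coil_effect,tmi_effect Named per-parameter additive coefficients
#'   for the post-upgrade coil indicator and the total motion index.
#' @param coil_changeover Study time (years) at which the coil epoch flips.
#' @param entry_window Width (years) of the uniform study-entry window.
#' @param tmi_meanlog,tmi_sdlog,tmi_asd_ratio Lognormal TMI parameters; ASD
#'   means are multiplied by `tmi_asd_ratio`.
#' @param asd_shift Deviation shift delta, in residual-SD units (scalar or
#'   per-feature).
#' @param asd_scale Variance inflation kappa (>= 1).
#' @param shift_sign Named per-parameter sign of the shift (FA down,
#'   diffusivities up).
#' @param phenotype_link Named correlations (`fsiq`, `piq`, `viq`, `srs`)
#'   between ASD phenotype and true deviation magnitude.
#' @param phenotype_moments Tibble of per-group phenotype means/SDs.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(spec = default_feature_spec(),
                          visit_structure = default_visit_structure(),
                          age_range = c(3.1, 36.8),
                          interval_mean = 2.6,
                          interval_sd = 0.9,
                          trajectory = default_trajectories(spec),
                          resid_sd = default_param_scale("resid"),
                          subject_sd = default_param_scale("subject"),
                          param_cor = default_param_cor(),
                          roi_cor = 0.2,
                          coil_effect = c(FA = 0.006, MD = -0.008,
                                          AD = -0.008, RD = -0.008),
                          tmi_effect = c(FA = -0.004, MD = 0.005,
                                         AD = 0.005, RD = 0.005),
                          coil_changeover = 2.5,
                          entry_window = 7,
                          tmi_meanlog = 0,
                          tmi_sdlog = 0.4,
                          tmi_asd_ratio = 1.25,
                          asd_shift = 0,
                          asd_scale = 1,
                          shift_sign = c(FA = -1, MD = 1, AD = 1, RD = 1),
                          phenotype_link = c(fsiq = -0.28, piq = -0.27,
                                             viq = -0.21, srs = 0.12),
                          phenotype_moments = default_phenotype_moments()) {
  stopifnot(inherits(spec, "feature_spec"))
  if (nrow(visit_structure) == 0) stop("visit_structure is empty", call. = FALSE)
  if (interval_mean <= 0) stop("interval_mean must be > 0", call. = FALSE)
  if (asd_scale < 1) stop("asd_scale (kappa) must be >= 1", call. = FALSE)
  if (any(abs(phenotype_link) >= 1)) {
    stop("phenotype_link correlations must lie in (-1, 1)", call. = FALSE)
  }
  cfg <- list(
    spec = spec, visit_structure = visit_structure, age_range = age_range,
    interval_mean = interval_mean, interval_sd = interval_sd,
    trajectory = trajectory,
    resid_sd = expand_by_parameter(resid_sd, spec),
    subject_sd = expand_by_parameter(subject_sd, spec),
    param_cor = param_cor, roi_cor = roi_cor,
    coil_effect = expand_by_parameter(coil_effect, spec),
    tmi_effect = expand_by_parameter(tmi_effect, spec),
    coil_changeover = coil_changeover, entry_window = entry_window,
    tmi_meanlog = tmi_meanlog, tmi_sdlog = tmi_sdlog,
    tmi_asd_ratio = tmi_asd_ratio,
    asd_shift = expand_by_feature(asd_shift, spec),
    asd_scale = asd_scale,
    shift_sign = expand_by_parameter(shift_sign, spec),
    phenotype_link = phenotype_link,
    phenotype_moments = phenotype_moments)
  cfg$Ccor <- residual_correlation_matrix(cfg)
  ev <- eigen(cfg$Ccor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("residual covariance specification is not positive definite",
         call. = FALSE)
  }
  cfg$Sigma <- cfg$Ccor * tcrossprod(cfg$resid_sd)
  class(cfg) <- "cohort_config"
  cfg
}

default_phenotype_moments <- function() {
  tibble::tibble(
    variable = rep(c("fsiq", "piq", "viq", "srs_total_raw"), each = 2),
    group = rep(c("ASD", "TDC"), 4),
    mean = c(99.42, 118.17, 102.24, 116.34, 95.06, 114.72, 99.73, 15.57),
    sd = c(17.70, 13.23, 18.10, 14.76, 21.63, 13.21, 30.30, 11.79))
}

# expand a per-parameter named vector (or scalar, or per-feature vector)
# to one value per feature in spec order
expand_by_parameter <- function(x, spec) {
  if (length(x) == nrow(spec) && !is.null(names(x)) &&
      all(names(x) == spec$feature)) return(x)
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.double(x), nrow(spec)), spec$feature))
  }
  if (!is.null(names(x)) && all(spec$parameter %in% names(x))) {
    return(stats::setNames(as.double(x[spec$parameter]), spec$feature))
  }
  if (length(x) == nrow(spec)) {
    return(stats::setNames(as.double(x), spec$feature))
  }
  stop("cannot expand value to one entry per feature", call. = FALSE)
}

expand_by_feature <- function(x, spec) {
  if (length(x) == 1) {
    return(stats::setNames(rep(as.double(x), nrow(spec)), spec$feature))
  }
  expand_by_parameter(x, spec)
}

# Kronecker-structured residual correlation: cross-ROI equicorrelation x
# within-ROI parameter block. PD whenever both factors are PD; the
# covariance is obtained by scaling with per-feature SDs (which may be 0
# for degenerate noise-free configurations).
residual_correlation_matrix <- function(cfg) {
  spec <- cfg$spec
  rois <- unique(spec$roi)
  pars <- unique(spec$parameter)
  R_roi <- (1 - cfg$roi_cor) * diag(length(rois)) +
    cfg$roi_cor * matrix(1, length(rois), length(rois))
  dimnames(R_roi) <- list(rois, rois)
  Rp <- cfg$param_cor[pars, pars, drop = FALSE]
  m <- nrow(spec)
  C <- matrix(0, m, m, dimnames = list(spec$feature, spec$feature))
  for (i in seq_len(m)) {
    C[i, ] <- R_roi[spec$roi[i], spec$roi] * Rp[spec$parameter[i], spec$parameter]
  }
  C
}

eval_trajectory <- function(trajectory, feature, age) {
  row <- trajectory[trajectory$feature == feature, , drop = FALSE]
  if (nrow(row) != 1) stop("no trajectory parameters for feature ", feature,
                           call. = FALSE)
  row$a + row$b * exp(-age / row$c)
}

#' Sample the visit schedule of an accelerated longitudinal design
#'
#' Baseline ages are uniform on `age_range`; successive inter-scan gaps are
#' Gamma with the configured mean/SD, so within-subject ages are strictly
#' increasing by construction. Study-entry times (used for the coil-epoch
#' proxy) are uniform on the entry window.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Tibble: `subject_id`, `group`, `scan_index`, `age`, `study_time`.
#' @export
sample_design <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  vs <- config$visit_structure
  if (nrow(vs) == 0) stop("visit_structure is empty", call. = FALSE)
  fixed_gaps <- config$interval_sd <= 0
  shape <- if (fixed_gaps) Inf else (config$interval_mean / config$interval_sd)^2
  rate <- if (fixed_gaps) Inf else config$interval_mean / config$interval_sd^2
  withr::with_seed(seed, {
    subj <- tibble::tibble(
      group = rep(vs$group, vs$n_subjects),
      n_scans = rep(vs$n_scans, vs$n_subjects))
    subj <- subj[order(subj$group, -subj$n_scans), , drop = FALSE]
    counts <- stats::ave(seq_len(nrow(subj)), subj$group, FUN = seq_along)
    subj$subject_id <- sprintf("%s%03d", subj$group, counts)
    subj$age0 <- stats::runif(nrow(subj), config$age_range[1], config$age_range[2])
    subj$entry <- stats::runif(nrow(subj), 0, config$entry_window)
    rows <- purrr::pmap(subj, function(group, n_scans, subject_id, age0, entry) {
      gaps <- if (n_scans <= 1) {
        numeric(0)
      } else if (fixed_gaps) {
        rep(config$interval_mean, n_scans - 1)
      } else {
        stats::rgamma(n_scans - 1, shape = shape, rate = rate)
      }
      offs <- c(0, cumsum(gaps))
      tibble::tibble(subject_id = subject_id, group = group,
                     scan_index = seq_len(n_scans),
                     age = age0 + offs, study_time = entry + offs)
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate regional microstructure values along a visit schedule
#'
#' Each measurement decomposes exactly as the analysis assumes:
#' `value = f_j(age) + u_sj + beta_coil * coil + beta_tmi * tmi + eps_stj`,
#' with per-feature subject random intercepts `u_sj` and within-scan
#' residual vectors drawn from the configured multivariate normal. TDC
#' residuals have mean zero; ASD residuals are shifted by
#' `asd_shift * shift_sign * resid_sd` and scaled by `asd_scale`. FA is
#' clipped to \[0, 1\] and diffusivities floored at a small positive value.
#'
#' @param design Schedule from [sample_design()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return List: `cohort` (long tibble) and `truth` (ground-truth list with
#'   trajectory parameters, true covariance, subject effects, shift vector
#'   and per-subject latent deviation magnitudes).
#' @export
simulate_trajectory_values <- function(design, config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  spec <- config$spec
  m <- nrow(spec)
  Sigma <- config$Sigma
  cholC <- chol(config$Ccor)
  sd_e <- config$resid_sd
  shift <- config$asd_shift * config$shift_sign * sd_e
  subjects <- dplyr::distinct(design, .data$subject_id, .data$group)
  S <- nrow(subjects)
  n <- nrow(design)

  withr::with_seed(seed, {
    # nuisance covariates
    coil <- ifelse(design$study_time < config$coil_changeover, "pre", "post")
    mu_tmi <- config$tmi_meanlog +
      log(ifelse(design$group == "ASD", config$tmi_asd_ratio, 1))
    tmi <- stats::rlnorm(n, meanlog = mu_tmi, sdlog = config$tmi_sdlog)

    # subject random intercepts, one per (subject, feature)
    U <- matrix(stats::rnorm(S * m), S, m) *
      matrix(config$subject_sd, S, m, byrow = TRUE)
    rownames(U) <- subjects$subject_id

    # within-scan residual vectors (correlated draw, column-scaled by SDs)
    E <- (matrix(stats::rnorm(n * m), n, m) %*% cholC) *
      matrix(sd_e, n, m, byrow = TRUE)
    asd <- design$group == "ASD"
    if (any(asd)) {
      E[asd, ] <- E[asd, , drop = FALSE] * config$asd_scale +
        matrix(shift, sum(asd), m, byrow = TRUE)
    }
  })

  # normative trajectory values, feature-major
  Fmat <- vapply(seq_len(m), function(j) {
    eval_trajectory(config$trajectory, spec$feature[j], design$age)
  }, numeric(n))
  cov_term <- outer(as.numeric(coil == "post"), config$coil_effect) +
    outer(tmi, config$tmi_effect)
  Y <- Fmat + U[design$subject_id, , drop = FALSE] + cov_term + E

  # physical ranges
  fa_cols <- which(spec$parameter == "FA")
  diff_cols <- which(spec$parameter != "FA")
  Y[, fa_cols] <- pmin(pmax(Y[, fa_cols, drop = FALSE], 0), 1)
  Y[, diff_cols] <- pmax(Y[, diff_cols, drop = FALSE], 1e-6)

  cohort <- tibble::tibble(
    subject_id = rep(design$subject_id, each = m),
    group = rep(design$group, each = m),
    scan_index = rep(design$scan_index, each = m),
    age = rep(design$age, each = m),
    coil = rep(coil, each = m),
    tmi = rep(tmi, each = m),
    roi = rep(spec$roi, n),
    parameter = rep(spec$parameter, n),
    value = as.vector(t(Y)))

  # latent per-subject deviation vector: mean residual shift (ASD) plus the
  # subject's own random intercept; its Mahalanobis norm under the true
  # residual covariance is the deviation magnitude phenotypes link to
  Dlat <- U + outer(as.numeric(subjects$group == "ASD"), shift)
  pos <- sd_e > 0
  if (!any(pos)) {
    dev_mag <- rep(0, S)
  } else {
    Dstd <- Dlat[, pos, drop = FALSE] /
      matrix(sd_e[pos], S, sum(pos), byrow = TRUE)
    Cinv <- chol2inv(chol(config$Ccor[pos, pos, drop = FALSE]))
    dev_mag <- sqrt(rowSums((Dstd %*% Cinv) * Dstd))
  }
  truth <- list(
    spec = spec,
    trajectory = config$trajectory,
    Sigma = Sigma,
    subject_effects = U,
    shift = shift,
    subjects = tibble::tibble(
      subject_id = subjects$subject_id, group = subjects$group,
      deviation_magnitude = dev_mag))
  list(cohort = cohort, truth = truth)
}

#' Simulate phenotypes linked to latent deviation magnitude
#'
#' IQ indices (FSIQ, PIQ, VIQ) and SRS total raw scores are drawn with the
#' configured per-group means/SDs. Within the ASD group each variable mixes
#' the standardized latent deviation magnitude with independent noise so
#' its population correlation with true deviation equals the configured
#' link (negative for IQ, positive for SRS); TDC phenotypes are pure noise
#' around the TDC moments.
#'
#' @param truth Ground truth from [simulate_trajectory_values()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Tibble: `subject_id`, `fsiq`, `piq`, `viq`, `srs_total_raw`.
#' @export
simulate_phenotypes <- function(truth, config, seed) {
  if (any(abs(config$phenotype_link) >= 1)) {
    stop("phenotype_link correlations must lie in (-1, 1)", call. = FALSE)
  }
  subj <- truth$subjects
  links <- c(fsiq = unname(config$phenotype_link["fsiq"]),
             piq = unname(config$phenotype_link["piq"]),
             viq = unname(config$phenotype_link["viq"]),
             srs_total_raw = unname(config$phenotype_link["srs"]))
  mom <- config$phenotype_moments
  out <- tibble::tibble(subject_id = subj$subject_id)
  withr::with_seed(seed, {
    for (v in names(links)) {
      vals <- numeric(nrow(subj))
      for (g in unique(subj$group)) {
        idx <- subj$group == g
        mrow <- mom[mom$variable == v & mom$group == g, , drop = FALSE]
        mu <- if (nrow(mrow)) mrow$mean else 100
        sdv <- if (nrow(mrow)) mrow$sd else 15
        r <- if (g == "ASD") links[[v]] else 0
        z <- as.numeric(scale(subj$deviation_magnitude[idx]))
        if (any(!is.finite(z))) z <- rep(0, sum(idx))
        e <- stats::rnorm(sum(idx))
        vals[idx] <- mu + sdv * (r * z + sqrt(1 - r^2) * e)
      }
      out[[v]] <- vals
    }
  })
  out
}

#' Generate a complete synthetic cohort
#'
#' Composes [sample_design()], [simulate_trajectory_values()] and
#' [simulate_phenotypes()]; a pure function of `(config, seed)`, so the
#' same pair reproduces bitwise-identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; stage seeds are derived deterministically.
#' @return List of class `sim_cohort`: `cohort`, `phenotypes`, `truth`,
#'   `design`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  seed <- as.integer(seed)
  design <- sample_design(config, seed)
  sim <- simulate_trajectory_values(design, config, seed + 1000003L)
  phen <- simulate_phenotypes(sim$truth, config, seed + 2000003L)
  structure(list(cohort = sim$cohort, phenotypes = phen, truth = sim$truth,
                 design = design, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  n_sub <- dplyr::n_distinct(x$cohort$subject_id)
  n_scan <- nrow(dplyr::distinct(x$cohort, .data$subject_id, .data$scan_index))
  cat("Synthetic longitudinal cohort (seed ", x$seed, ")\n", sep = "")
  cat("  ", n_sub, " subjects, ", n_scan, " scans, ",
      nrow(x$truth$spec), " features\n", sep = "")
  invisible(x)
}
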