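# ---- internal penalized GLS machinery ------------------------------------

# crossproducts under the compound-symmetry working covariance
# V = I + rho * J (block per subject): A'V^-1 A, A'V^-1 y, y'V^-1 y, log|V|
cs_cross <- function(A, y, subj_index, n_i, rho) {
  AtA <- crossprod(A)
  Aty <- drop(crossprod(A, y))
  yty <- sum(y * y)
  logdetV <- 0
  if (rho > 0) {
    As <- rowsum(A, subj_index, reorder = TRUE)
    ys <- drop(rowsum(y, subj_index, reorder = TRUE))
    cc <- rho / (1 + n_i * rho)
    AtA <- AtA - crossprod(As * sqrt(cc))
    Aty <- Aty - drop(crossprod(As, cc * ys))
    yty <- yty - sum(cc * ys^2)
    logdetV <- sum(log1p(n_i * rho))
  }
  list(AtA = AtA, Aty = Aty, yty = yty, logdetV = logdetV)
}

# penalized GLS solve at fixed lambda; returns coefficients and the
# criteria needed for smoothing selection
pls_solve <- function(cross, lambda, p_fixed, q_wiggly, n) {
  pen <- c(rep(0, p_fixed), rep(lambda, q_wiggly))
  M <- cross$AtA + diag(pen, nrow = p_fixed + q_wiggly)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) stop("penalized system is singular", call. = FALSE)
  coef <- backsolve(R, backsolve(R, cross$Aty, transpose = TRUE))
  rss_pen <- max(cross$yty - sum(coef * cross$Aty), 0)
  sig2 <- max(rss_pen, 1e-300) / max(n - p_fixed, 1)
  reml <- (n - p_fixed) * log(sig2) + 2 * sum(log(diag(R))) -
    q_wiggly * log(lambda) + cross$logdetV
  Minv_AtA <- backsolve(R, backsolve(R, cross$AtA, transpose = TRUE))
  edf <- sum(diag(Minv_AtA))
  quad <- sum(coef * (cross$AtA %*% coef))
  rss_gls <- max(cross$yty - 2 * sum(coef * cross$Aty) + quad, 0)
  gcv <- n * max(rss_gls, 1e-300) / max(n - edf, 0.1)^2
  list(coef = coef, reml = reml, gcv = gcv, edf = edf, rss_gls = rss_gls)
}

# method-of-moments variance components from marginal residuals
# (one-way unbalanced ANOVA on the subject grouping)
mom_variance <- function(e, subj_index, n_i, y_scale2 = 1) {
  n <- length(e)
  S <- length(n_i)
  ebar_i <- drop(rowsum(e, subj_index, reorder = TRUE)) / n_i
  ssw <- sum((e - ebar_i[subj_index])^2)
  sigma_e2 <- if (n > S) ssw / (n - S) else stats::var(e)
  ebar <- mean(e)
  ssb <- sum(n_i * (ebar_i - ebar)^2)
  denom <- n - sum(n_i^2) / n
  sigma_u2 <- if (denom > 0 && S > 1) {
    max(0, (ssb - (S - 1) * sigma_e2) / denom)
  } else 0
  # residuals that are numerically zero relative to the data scale would
  # make the variance ratio a quotient of rounding noise: treat as exact fit
  if (!is.finite(sigma_e2) || sigma_e2 <= 1e-22 * y_scale2) {
    sigma_e2 <- max(sigma_e2, 0)
    rho <- 0
  } else {
    rho <- sigma_u2 / sigma_e2
  }
  list(sigma_e2 = sigma_e2, sigma_u2 = sigma_u2, rho = rho)
}

# assemble fixed (null-space spline + covariates) and wiggly design blocks
design_blocks <- function(B, trans, coil_ind, tmi, use_coil, use_tmi) {
  X <- B %*% trans$U0
  if (use_coil) X <- cbind(X, coil = coil_ind)
  if (use_tmi) X <- cbind(X, tmi = tmi)
  Z <- B %*% trans$U1
  Z <- Z * matrix(trans$dinv, nrow(Z), ncol(Z), byrow = TRUE)
  list(X = X, Z = Z)
}

# ---- fitting --------------------------------------------------------------

#' Fit a normative developmental trajectory for one feature
#'
#' Fits the reference growth curve on typically developing control (TDC)
#' data for a single (ROI, parameter) feature: a penalized cubic B-spline
#' smooth of age plus additive head-coil and motion (TMI) covariates, with
#' a per-subject random intercept for the repeated measurements. The
#' smoothing parameter is selected by grid REML (default) or GCV; the
#' random-intercept and residual variances are estimated by an iterated
#' method-of-moments scheme on the marginal residuals. The fit is a
#' deterministic function of the data and configuration.
#'
#' @param data Either a long cohort tibble (in which case `feature` selects
#'   the ROI/parameter and only `group == "TDC"` rows are used), or a
#'   per-scan data frame with columns `subject_id`, `age`, `coil`, `tmi`,
#'   `value`.
#' @param feature Feature label `"roi.PARAM"` (or `c(roi, parameter)`)
#'   when `data` is a long cohort.
#' @param config A [smoother_config()].
#' @return An object of class `normative_fit`.
#' @export
fit_normative <- function(data, feature = NULL, config = smoother_config()) {
  d <- extract_feature_data(data, feature)
  n <- nrow(d)
  n_subjects <- length(unique(d$subject_id))
  if (n_subjects < config$min_subjects) {
    stop("insufficient data: ", n_subjects, " subjects (minimum ",
         config$min_subjects, ")", call. = FALSE)
  }
  knots <- spline_knots(d$age, config$n_knots)
  B <- spline_eval(knots, d$age)
  P <- penalty_gram(knots, config$penalty_order)
  eg <- eigen(P, symmetric = TRUE)
  tol_null <- max(eg$values) * 1e-9
  null_idx <- which(eg$values <= tol_null)
  pos_idx <- which(eg$values > tol_null)
  trans <- list(U0 = eg$vectors[, null_idx, drop = FALSE],
                U1 = eg$vectors[, pos_idx, drop = FALSE],
                dinv = 1 / sqrt(eg$values[pos_idx]))

  coil_levels <- sort(unique(as.character(d$coil)))
  use_coil <- length(coil_levels) > 1
  coil_ind <- if (use_coil) as.numeric(d$coil == coil_levels[2]) else rep(0, n)
  use_tmi <- stats::sd(d$tmi) > 0
  blocks <- design_blocks(B, trans, coil_ind, d$tmi, use_coil, use_tmi)
  A <- cbind(blocks$X, blocks$Z)
  p_fixed <- ncol(blocks$X)
  q_wiggly <- ncol(blocks$Z)

  subj_f <- factor(d$subject_id)
  subj_index <- as.integer(subj_f)
  n_i <- tabulate(subj_index, nbins = nlevels(subj_f))

  rho <- 0
  lambda <- config$lambda
  fitted_sol <- NULL
  converged <- FALSE
  iterations <- 0L
  vc <- list(sigma_e2 = 0, sigma_u2 = 0, rho = 0)
  for (iter in seq_len(config$max_iter)) {
    iterations <- iter
    cross <- cs_cross(A, d$value, subj_index, n_i, rho)
    if (config$selection == "fixed") {
      sol <- pls_solve(cross, config$lambda, p_fixed, q_wiggly, n)
      lambda <- config$lambda
    } else if (iter <= 3) {
      # re-select the smoothing parameter only in the first sweeps; freezing
      # it afterwards makes the variance-ratio update a smooth fixed-point
      # iteration (grid selection flips discretely otherwise)
      crits <- vapply(config$lambda_grid, function(l) {
        s <- pls_solve(cross, l, p_fixed, q_wiggly, n)
        if (config$selection == "REML") s$reml else s$gcv
      }, numeric(1))
      lambda <- config$lambda_grid[which.min(crits)]
      sol <- pls_solve(cross, lambda, p_fixed, q_wiggly, n)
    } else {
      sol <- pls_solve(cross, lambda, p_fixed, q_wiggly, n)
    }
    fitted_sol <- sol
    e <- d$value - drop(A %*% sol$coef)
    vc <- mom_variance(e, subj_index, n_i,
                       y_scale2 = mean(d$value^2) + stats::var(d$value))
    rho_new <- if (iter > 3) (rho + vc$rho) / 2 else vc$rho
    if (abs(rho_new - rho) < config$tol * (1 + rho)) {
      rho <- rho_new
      converged <- TRUE
      break
    }
    rho <- rho_new
  }
  if (!converged) {
    stop("variance-component iteration did not converge for feature ",
         if (is.null(feature)) "(data)" else paste(feature, collapse = "."),
         call. = FALSE)
  }

  coef <- fitted_sol$coef
  p0 <- ncol(trans$U0)
  alpha0 <- coef[seq_len(p0)]
  k <- p0
  beta_coil <- 0
  beta_tmi <- 0
  if (use_coil) { k <- k + 1L; beta_coil <- coef[k] }
  if (use_tmi) { k <- k + 1L; beta_tmi <- coef[k] }
  b <- coef[seq.int(p_fixed + 1L, p_fixed + q_wiggly)]
  theta <- drop(trans$U0 %*% alpha0 + trans$U1 %*% (b * trans$dinv))

  e <- d$value - drop(A %*% coef)
  df_resid <- max(n - fitted_sol$edf, 1)
  structure(list(
    feature = if (is.null(feature)) NA_character_ else paste(feature, collapse = "."),
    knots = knots, penalty_order = config$penalty_order,
    theta = theta, beta_coil = beta_coil, beta_tmi = beta_tmi,
    coil_levels = coil_levels, use_coil = use_coil, use_tmi = use_tmi,
    lambda = lambda, rho = rho,
    sigma_u = sqrt(vc$sigma_u2), sigma_eps = sqrt(vc$sigma_e2),
    sigma_resid = sqrt(sum(e^2) / df_resid),
    edf = fitted_sol$edf,
    age_range = range(d$age),
    n_scans = n, n_subjects = n_subjects,
    iterations = iterations, converged = converged,
    trans = trans, config = config),
    class = "normative_fit")
}

extract_feature_data <- function(data, feature) {
  if (all(c("roi", "parameter", "value") %in% names(data))) {
    if (is.null(feature)) {
      feats <- unique(paste(data$roi, data$parameter, sep = "."))
      if (length(feats) > 1) {
        stop("long cohort data: supply `feature` to select one of ",
             length(feats), " features", call. = FALSE)
      }
      feature <- feats
    }
    flab <- paste(feature, collapse = ".")
    d <- data[paste(data$roi, data$parameter, sep = ".") == flab, , drop = FALSE]
    if ("group" %in% names(d)) d <- d[d$group == "TDC", , drop = FALSE]
    if (nrow(d) == 0) stop("no TDC rows for feature ", flab, call. = FALSE)
    tibble::tibble(subject_id = d$subject_id, age = d$age, coil = d$coil,
                   tmi = d$tmi, value = d$value)
  } else {
    need <- c("subject_id", "age", "coil", "tmi", "value")
    missing <- setdiff(need, names(data))
    if (length(missing) > 0) {
      stop("fit data missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tibble::as_tibble(data[, need])
  }
}

#' Predict the normative mean at given ages and covariates
#'
#' Fixed-effects prediction only (spline evaluated at age plus covariate
#' terms); subject random intercepts are excluded, so the prediction is the
#' population normative curve.
#'
#' @param fit A `normative_fit`.
#' @param age Ages in years.
#' @param coil Coil labels (recycled); defaults to the fit's baseline level.
#' @param tmi Total motion index values (recycled), default 0.
#' @return Numeric vector of predictions.
#' @export
predict_mean <- function(fit, age, coil = NULL, tmi = 0) {
  stopifnot(inherits(fit, "normative_fit"))
  lo <- fit$age_range[1]
  hi <- fit$age_range[2]
  out_of_range <- age < lo | age > hi
  if (any(out_of_range)) {
    if (fit$config$extrapolation == "strict") {
      stop("age(s) outside training range [", signif(lo, 4), ", ",
           signif(hi, 4), "]", call. = FALSE)
    }
    warning("clamping ", sum(out_of_range),
            " age(s) to the training range", call. = FALSE)
    age <- pmin(pmax(age, lo), hi)
  }
  B <- spline_eval(fit$knots, age)
  pred <- drop(B %*% fit$theta)
  if (fit$use_coil) {
    if (is.null(coil)) coil <- fit$coil_levels[1]
    pred <- pred + fit$beta_coil * as.numeric(rep_len(as.character(coil),
                                                      length(age)) ==
                                                fit$coil_levels[2])
  }
  pred + fit$beta_tmi * rep_len(tmi, length(age))
}

#' Marginal residuals of scans against a normative fit
#'
#' Residual = observed value minus the fixed-effects prediction at the
#' scan's own age and covariates, so deviations are covariate-adjusted.
#' Order-preserving: one residual per input row.
#'
#' @param fit A `normative_fit`.
#' @param data Long cohort rows for the fit's feature, or a per-scan data
#'   frame with `age`, `coil`, `tmi`, `value`.
#' @return Numeric vector of residuals.
#' @export
marginal_residuals <- function(fit, data) {
  if (all(c("roi", "parameter") %in% names(data)) && !is.na(fit$feature)) {
    data <- data[paste(data$roi, data$parameter, sep = ".") == fit$feature, ,
                 drop = FALSE]
  }
  data$value - predict_mean(fit, data$age, data$coil, data$tmi)
}

# refit coefficients on a row subset with knots, covariate structure,
# lambda and rho held fixed at the reference fit's values; returns
# predictions for an evaluation set and the residual scale of the fit rows
pls_refit <- function(fit, train, eval_rows = NULL) {
  B <- spline_eval(fit$knots, train$age)
  coil_ind <- if (fit$use_coil) {
    as.numeric(as.character(train$coil) == fit$coil_levels[2])
  } else rep(0, nrow(train))
  blocks <- design_blocks(B, fit$trans, coil_ind, train$tmi,
                          fit$use_coil, fit$use_tmi)
  A <- cbind(blocks$X, blocks$Z)
  p_fixed <- ncol(blocks$X)
  q_wiggly <- ncol(blocks$Z)
  subj_f <- factor(train$subject_id)
  subj_index <- as.integer(subj_f)
  n_i <- tabulate(subj_index, nbins = nlevels(subj_f))
  cross <- cs_cross(A, train$value, subj_index, n_i, fit$rho)
  sol <- pls_solve(cross, fit$lambda, p_fixed, q_wiggly, nrow(train))
  resid_train <- train$value - drop(A %*% sol$coef)
  sigma_resid <- sqrt(sum(resid_train^2) / max(nrow(train) - sol$edf, 1))
  out <- list(resid_train = resid_train, sigma_resid = sigma_resid,
              edf = sol$edf)
  if (!is.null(eval_rows)) {
    Be <- spline_eval(fit$knots, eval_rows$age)
    ce <- if (fit$use_coil) {
      as.numeric(as.character(eval_rows$coil) == fit$coil_levels[2])
    } else rep(0, nrow(eval_rows))
    be <- design_blocks(Be, fit$trans, ce, eval_rows$tmi,
                        fit$use_coil, fit$use_tmi)
    Ae <- cbind(be$X, be$Z)
    out$resid_eval <- eval_rows$value - drop(Ae %*% sol$coef)
  }
  out
}

#' @export
print.normative_fit <- function(x, ...) {
  cat("Normative trajectory fit", if (!is.na(x$feature)) paste0(" [", x$feature, "]"),
      "\n", sep = "")
  cat(sprintf("  %d scans from %d subjects, ages %.2f-%.2f\n",
              x$n_scans, x$n_subjects, x$age_range[1], x$age_range[2]))
  cat(sprintf("  lambda = %.3g, edf = %.2f, sigma_u = %.4g, sigma_resid = %.4g\n",
              x$lambda, x$edf, x$sigma_u, x$sigma_resid))
  invisible(x)
}

#' Fit normative trajectories for every feature of a spec
#'
#' @param cohort Long cohort tibble (TDC rows are selected internally).
#' @param spec A [feature_spec()].
#' @param config A [smoother_config()].
#' @return Named list of `normative_fit` objects, one per feature.
#' @export
fit_normative_set <- function(cohort, spec = default_feature_spec(),
                              config = smoother_config()) {
  fits <- lapply(seq_len(nrow(spec)), function(j) {
    fit_normative(cohort, feature = c(spec$roi[j], spec$parameter[j]),
                  config = config)
  })
  stats::setNames(fits, spec$feature)
}

#' Serialize normative fits to JSON
#'
#' Writes knots, coefficients, covariate terms, smoothing parameter and
#' variance components so that fitting and deviation scoring can run as
#' separate stages.
#'
#' @param fits Named list from [fit_normative_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normative_fits <- function(fits, path) {
  ser <- lapply(fits, function(f) {
    f[c("feature", "knots", "penalty_order", "theta", "beta_coil", "beta_tmi",
        "coil_levels", "use_coil", "use_tmi", "lambda", "rho", "sigma_u",
        "sigma_eps", "sigma_resid", "edf", "age_range", "n_scans",
        "n_subjects")]
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read normative fits serialized by [write_normative_fits()]
#'
#' Restored fits support prediction and residual computation (not
#' leave-one-out refitting, which needs the training data anyway).
#'
#' @param path JSON path.
#' @param config [smoother_config()] recorded with the restored fits.
#' @return Named list of `normative_fit` objects.
#' @export
read_normative_fits <- function(path, config = smoother_config()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(f) {
    f$knots <- as.numeric(f$knots)
    f$theta <- as.numeric(f$theta)
    f$age_range <- as.numeric(f$age_range)
    f$coil_levels <- as.character(f$coil_levels)
    f$config <- config
    class(f) <- "normative_fit"
    f
  })
}
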