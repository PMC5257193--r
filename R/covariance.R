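#' Construct a covariance model from a given matrix
#'
#' Wraps a symmetric positive-definite matrix with its Cholesky factor so
#' Mahalanobis distances are computed by triangular solves, never an
#' explicit inverse.
#'
#' @param S Symmetric positive-definite matrix.
#' @param estimator Label recording how `S` was obtained.
#' @param gamma Shrinkage intensity in \[0, 1\] (0 when not applicable).
#' @param n Number of rows used in estimation (NA for fixed matrices).
#' @return An object of class `covariance_model`.
#' @export
covariance_model <- function(S, estimator = "fixed", gamma = 0, n = NA_integer_) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(abs(S), 1e-300)) {
    stop("covariance must be a symmetric square matrix", call. = FALSE)
  }
  S <- (S + t(S)) / 2
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    stop("covariance is not positive definite",
         if (estimator == "sample") " (sample estimator with too few rows; use the shrinkage estimator)",
         call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  structure(list(S = S, chol = R, estimator = estimator, gamma = gamma,
                 n = n, m = nrow(S),
                 condition = max(ev) / min(ev)),
            class = "covariance_model")
}

#' Estimate the reference residual covariance
#'
#' Estimates the scan-level covariance of TDC marginal residuals, the `S`
#' of the Mahalanobis distance. The default estimator shrinks the sample
#' covariance toward its diagonal with an analytic risk-minimizing
#' intensity (off-diagonal correlation shrinkage): with m = 76 features and
#' ~149 reference scans the raw sample covariance is ill-conditioned.
#'
#' @param residuals A scans-by-features residual matrix (or the `R`
#'   component of [assemble_residual_matrix()] output).
#' @param estimator `"shrinkage"` (default), `"sample"`, or `"diagonal"`.
#' @param gamma Shrinkage intensity; `NULL` selects it analytically.
#' @return A `covariance_model`.
#' @export
estimate_covariance <- function(residuals,
                                estimator = c("shrinkage", "sample", "diagonal"),
                                gamma = NULL) {
  estimator <- match.arg(estimator)
  X <- if (is.list(residuals) && !is.data.frame(residuals)) residuals$R else residuals
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  if (n < 2) stop("need at least 2 residual rows", call. = FALSE)
  v <- apply(X, 2, stats::var)
  zero <- which(v <= 1e-20)
  if (length(zero) > 0) {
    nm <- colnames(X)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("degenerate feature(s) with zero residual variance: ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
  Ssamp <- stats::cov(X)
  if (estimator == "sample") {
    return(covariance_model(Ssamp, "sample", 0, n))
  }
  if (estimator == "diagonal") {
    return(covariance_model(diag(v, m), "diagonal", 1, n))
  }
  if (is.null(gamma)) gamma <- shrinkage_intensity(X)
  S <- (1 - gamma) * Ssamp + gamma * diag(diag(Ssamp), m)
  covariance_model(S, "shrinkage", gamma, n)
}

# analytic diagonal-target shrinkage intensity: ratio of the summed
# estimation variance of the off-diagonal correlations to their summed
# squared magnitude, clamped to [0, 1]
shrinkage_intensity <- function(X) {
  n <- nrow(X)
  Xs <- scale(X)
  Rhat <- crossprod(Xs) / (n - 1)
  W2 <- crossprod(Xs^2) # sum over rows of (x_i x_j)^2 for standardized data
  var_r <- (n / ((n - 1)^3)) * (W2 - (crossprod(Xs))^2 / n)
  off <- upper.tri(Rhat)
  num <- sum(var_r[off])
  den <- sum(Rhat[off]^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Mahalanobis distance of residual vectors
#'
#' `D_M = sqrt((x - mu) S^-1 (x - mu)^T)`, with the residual vector already
#' centered on the normative prediction. Computed through the stored
#' Cholesky factor of `S` (a triangular solve), never an explicit inverse.
#' Reduces to the Euclidean norm under an identity covariance.
#'
#' @param x Numeric vector of length m, or a rows-by-m matrix of residual
#'   vectors.
#' @param cov A `covariance_model`.
#' @return Nonnegative scalar (or vector, one distance per row).
#' @export
mahalanobis_distance <- function(x, cov) {
  stopifnot(inherits(cov, "covariance_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != cov$m) {
    stop("residual vector has length ", ncol(x), " but covariance is ",
         cov$m, " x ", cov$m, call. = FALSE)
  }
  z <- backsolve(cov$chol, t(x), transpose = TRUE)
  sqrt(colSums(z^2))
}

#' Average per-scan distances into a subject-level distance
#'
#' The unweighted arithmetic mean over a subject's available time points
#' (1--4 scans), giving the single representative deviation value per
#' individual.
#'
#' @param per_scan Numeric vector of nonnegative per-scan distances.
#' @return Scalar mean.
#' @export
subject_mean_distance <- function(per_scan) {
  if (length(per_scan) == 0) stop("no per-scan distances", call. = FALSE)
  if (any(per_scan < 0)) stop("distances must be nonnegative", call. = FALSE)
  mean(per_scan)
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("Covariance model (%s): %d x %d, gamma = %.3f, n = %s, condition = %.3g\n",
              x$estimator, x$m, x$m, x$gamma, as.character(x$n), x$condition))
  invisible(x)
}
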