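#' Configure the normative smoother
#'
#' Cubic B-spline penalized regression with quantile-placed knots, an
#' integrated squared-derivative penalty (order `penalty_order`, so the
#' penalty null space spans polynomials up to degree `penalty_order - 1`),
#' a subject random intercept estimated by an iterated method-of-moments
#' scheme, and smoothing-parameter selection by grid REML (default), GCV,
#' or a fixed value.
#'
#' @param n_knots Number of quantile-placed knots (including the boundary
#'   knots) on the training ages. Basis dimension is `n_knots + 2`.
#' @param penalty_order Derivative order of the roughness penalty.
#' @param selection One of `"REML"`, `"GCV"`, `"fixed"`.
#' @param lambda Smoothing parameter used when `selection = "fixed"`.
#' @param lambda_grid Candidate smoothing parameters for REML/GCV.
#' @param tol Convergence tolerance of the variance-component iteration.
#' @param max_iter Maximum variance-component iterations.
#' @param min_subjects Minimum number of distinct training subjects.
#' @param extrapolation Out-of-range prediction policy: `"clamp"` predicts
#'   at the nearest boundary with a warning, `"strict"` errors.
#' @return A list of class `smoother_config`.
#' @export
smoother_config <- function(n_knots = 8,
                            penalty_order = 2,
                            selection = c("REML", "GCV", "fixed"),
                            lambda = 1,
                            lambda_grid = 10^seq(-4, 8, length.out = 25),
                            tol = 1e-5,
                            max_iter = 50,
                            min_subjects = 10,
                            extrapolation = c("clamp", "strict")) {
  selection <- match.arg(selection)
  extrapolation <- match.arg(extrapolation)
  if (n_knots < penalty_order + 1) {
    stop("n_knots must be at least penalty_order + 1", call. = FALSE)
  }
  if (any(lambda_grid <= 0) || lambda <= 0) {
    stop("smoothing parameters must be strictly positive", call. = FALSE)
  }
  structure(list(n_knots = n_knots, penalty_order = penalty_order,
                 selection = selection, lambda = lambda,
                 lambda_grid = sort(lambda_grid), tol = tol,
                 max_iter = max_iter, min_subjects = min_subjects,
                 extrapolation = extrapolation),
            class = "smoother_config")
}

# augmented knot vector for a clamped cubic B-spline on quantile knots
spline_knots <- function(ages, n_knots) {
  qs <- unname(stats::quantile(ages, probs = seq(0, 1, length.out = n_knots)))
  qs <- unique(qs)
  if (length(qs) < n_knots) {
    stop("degenerate design: fewer than ", n_knots, " distinct ages",
         call. = FALSE)
  }
  c(rep(qs[1], 3), qs, rep(qs[length(qs)], 3))
}

spline_eval <- function(knots, x, derivs = 0L) {
  lo <- knots[1]
  hi <- knots[length(knots)]
  x <- pmin(pmax(x, lo), hi)
  splines::splineDesign(knots, x, ord = 4L,
                        derivs = rep(as.integer(derivs), length(x)))
}

#' Build a cubic B-spline basis with a derivative roughness penalty
#'
#' The basis is a clamped cubic B-spline on quantile-placed knots; it forms
#' a partition of unity (rows sum to 1). The penalty is the exact Gram
#' matrix of order-`penalty_order` derivatives, computed by 3-point
#' Gauss-Legendre quadrature per knot interval (exact for the piecewise
#' polynomials involved), so constants -- and, for `penalty_order = 2`,
#' linear functions of age -- incur exactly zero penalty.
#'
#' @param ages Numeric vector of training ages.
#' @param config A [smoother_config()].
#' @return List: `B` (basis matrix), `P` (penalty matrix), `knots`
#'   (augmented knot vector), `nbasis`.
#' @export
build_spline_basis <- function(ages, config = smoother_config()) {
  knots <- spline_knots(ages, config$n_knots)
  B <- spline_eval(knots, ages)
  P <- penalty_gram(knots, config$penalty_order)
  list(B = B, P = P, knots = knots, nbasis = ncol(B))
}

# exact integral of products of order-d derivatives of the cubic B-splines
penalty_gram <- function(knots, order) {
  interior <- unique(knots)
  nb <- length(knots) - 4L
  P <- matrix(0, nb, nb)
  # 3-point Gauss-Legendre nodes/weights on [-1, 1]
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  for (i in seq_len(length(interior) - 1L)) {
    a <- interior[i]
    b <- interior[i + 1L]
    if (b <= a) next
    h <- (b - a) / 2
    xs <- a + h * (gx + 1)
    D <- splines::splineDesign(knots, xs, ord = 4L,
                               derivs = rep(as.integer(order), length(xs)))
    P <- P + h * crossprod(D * sqrt(gw), D * sqrt(gw))
  }
  (P + t(P)) / 2
}
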