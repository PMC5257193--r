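# build a per-scan TDC fitting frame directly
make_fit_data <- function(n_subj = 20, scans = 3, f = function(a) 0.5,
                          sigma = 0, subject_sd = 0, seed = 1,
                          coil = NULL, tmi = NULL) {
  withr::with_seed(seed, {
    age0 <- runif(n_subj, 4, 30)
    rows <- lapply(seq_len(n_subj), function(i) {
      a <- age0[i] + seq(0, by = 2.5, length.out = scans)
      tibble::tibble(subject_id = sprintf("S%03d", i), age = a)
    })
    d <- dplyr::bind_rows(rows)
    d$coil <- if (is.null(coil)) "pre" else coil(d)
    d$tmi <- if (is.null(tmi)) 0 else tmi(d)
    u <- rnorm(n_subj, 0, subject_sd)
    d$value <- f(d$age) + u[match(d$subject_id, sprintf("S%03d", seq_len(n_subj)))] +
      rnorm(nrow(d), 0, sigma)
    d
  })
}

test_that("constant data produce a constant fit with vanishing residual SD", {
  d <- make_fit_data(f = function(a) 0.5)
  fit <- fit_normative(d)
  expect_lt(fit$sigma_resid, 1e-8)
  ages <- seq(fit$age_range[1], fit$age_range[2], length.out = 5)
  expect_equal(predict_mean(fit, ages), rep(0.5, 5), tolerance = 1e-8)
})

test_that("a noiseless linear trend is recovered exactly (penalty null space)", {
  d <- make_fit_data(f = function(a) 0.30 + 0.01 * a)
  fit <- fit_normative(d)
  expect_equal(predict_mean(fit, 10), 0.40, tolerance = 1e-3)
  expect_equal(predict_mean(fit, 25), 0.55, tolerance = 1e-3)
})

test_that("covariate effects enter predictions linearly and exactly", {
  d <- make_fit_data(f = function(a) 0.4 + 0.005 * a, sigma = 0.01, seed = 3,
                     coil = function(d) rep(c("pre", "post"), length.out = nrow(d)),
                     tmi = function(d) runif(nrow(d), 0, 2))
  fit <- fit_normative(d)
  p0 <- predict_mean(fit, 15, coil = "pre", tmi = 0)
  p2 <- predict_mean(fit, 15, coil = "pre", tmi = 2)
  expect_equal(p2 - p0, 2 * fit$beta_tmi, tolerance = 1e-12)
  ppre <- predict_mean(fit, 15, coil = "pre", tmi = 1)
  ppost <- predict_mean(fit, 15, coil = "post", tmi = 1)
  expect_equal(abs(ppost - ppre), abs(fit$beta_coil), tolerance = 1e-12)
})

test_that("the prediction curve is continuous on a dense grid", {
  d <- make_fit_data(f = function(a) 0.55 - 0.25 * exp(-a / 5), sigma = 0.02,
                     subject_sd = 0.01, seed = 4)
  fit <- fit_normative(d)
  grid <- seq(fit$age_range[1], fit$age_range[2], by = 1e-3)
  pred <- predict_mean(fit, grid)
  # adjacent jumps are bounded by (max slope) * step: no discontinuities
  slope_bound <- max(abs(diff(pred) / 1e-3))
  expect_lt(slope_bound, 0.1)
  expect_lt(max(abs(diff(pred))), 0.1 * 1e-3)
})

test_that("as lambda grows the fit tends to the covariate-adjusted linear fit", {
  d <- make_fit_data(n_subj = 30, scans = 1,
                     f = function(a) 0.55 - 0.25 * exp(-a / 5),
                     sigma = 0.02, seed = 5,
                     tmi = function(d) runif(nrow(d), 0, 2))
  fit <- fit_normative(d, config = smoother_config(selection = "fixed",
                                                   lambda = 1e8))
  lmfit <- stats::lm(value ~ age + tmi, data = d)
  pred_spline <- predict_mean(fit, d$age, tmi = d$tmi)
  pred_lm <- unname(stats::predict(lmfit, d))
  expect_lt(max(abs(pred_spline - pred_lm)), 1e-4)
})

test_that("marginal residuals are exact differences and average to ~0 in-sample", {
  d <- make_fit_data(f = function(a) 0.5 + 0.004 * a, sigma = 0.02, seed = 6)
  fit <- fit_normative(d)
  r <- marginal_residuals(fit, d)
  expect_equal(r, d$value - predict_mean(fit, d$age, d$coil, d$tmi))
  expect_lt(abs(mean(r)), 1e-6 * stats::sd(d$value))

  d2 <- d[1, ]
  d2$value <- predict_mean(fit, d2$age, d2$coil, d2$tmi) + 0.05
  expect_equal(marginal_residuals(fit, d2), 0.05, tolerance = 1e-12)
})

test_that("fitting is deterministic and enforces the subject minimum", {
  d <- make_fit_data(f = function(a) 0.5, sigma = 0.01, subject_sd = 0.005,
                     seed = 7)
  f1 <- fit_normative(d)
  f2 <- fit_normative(d)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$lambda, f2$lambda)
  expect_error(fit_normative(d[d$subject_id %in% sprintf("S%03d", 1:5), ]),
               "insufficient")
})

test_that("extrapolation policy clamps with a warning or errors in strict mode", {
  d <- make_fit_data(f = function(a) 0.5, sigma = 0.01, seed = 8)
  fit <- fit_normative(d)
  expect_warning(p <- predict_mean(fit, fit$age_range[2] + 5), "clamp")
  expect_equal(p, suppressWarnings(predict_mean(fit, fit$age_range[2])))
  fit_strict <- fit_normative(d, config = smoother_config(extrapolation = "strict"))
  expect_error(predict_mean(fit_strict, fit_strict$age_range[2] + 5),
               "outside")
})

test_that("the normative curve agrees with an independent additive-model fit", {
  skip_if_not_installed("mgcv")
  d <- make_fit_data(n_subj = 57, scans = 3,
                     f = function(a) 0.55 - 0.25 * exp(-a / 5),
                     sigma = 0.02, subject_sd = 0.01, seed = 9,
                     tmi = function(d) runif(nrow(d), 0, 2))
  fit <- fit_normative(d)
  d$sid <- factor(d$subject_id)
  gm <- mgcv::gam(value ~ s(age, k = 10) + tmi + s(sid, bs = "re"),
                  data = d, method = "REML")
  grid <- data.frame(age = seq(6, 28, length.out = 50), tmi = 1,
                     sid = d$sid[1])
  pred_gam <- as.numeric(mgcv::predict.gam(gm, grid,
                                           exclude = "s(sid)", newdata.guaranteed = TRUE))
  pred_ours <- predict_mean(fit, grid$age, tmi = 1)
  rmse <- sqrt(mean((pred_gam - pred_ours)^2))
  expect_lt(rmse, 0.005)
})

test_that("fits serialize to JSON and restore to the same predictions", {
  cfg <- tiny_config()
  g <- generate_cohort(cfg, seed = 12)
  fits <- fit_normative_set(g$cohort, cfg$spec, fast_smoother())
  path <- withr::local_tempfile(fileext = ".json")
  write_normative_fits(fits, path)
  back <- read_normative_fits(path, fast_smoother())
  ages <- seq(8, 25, length.out = 7)
  for (f in names(fits)) {
    expect_equal(predict_mean(back[[f]], ages, tmi = 0.5),
                 predict_mean(fits[[f]], ages, tmi = 0.5), tolerance = 1e-12)
  }
})
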