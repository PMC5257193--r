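# cohort whose TDC group defines the curves and whose values can be
# perturbed feature-wise
scored_fixture <- function(seed = 21, shift = 0, scale = 1) {
  cfg <- effect_config(shift = shift, scale = scale)
  generate_cohort(cfg, seed = seed)
}

test_that("a cohort lying on the fitted curves gives a zero residual matrix", {
  g <- scored_fixture()
  spec <- small_spec()
  fits <- fit_normative_set(g$cohort, spec, fast_smoother())
  sc <- cohort_scans(g$cohort, spec)
  flat <- sc$info
  rows <- lapply(spec$feature, function(f) {
    out <- flat
    out$roi <- sub("\\..*$", "", f)
    out$parameter <- sub("^.*\\.", "", f)
    out$value <- predict_mean(fits[[f]], flat$age, flat$coil, flat$tmi)
    out
  })
  oncurve <- dplyr::bind_rows(rows)
  rm <- assemble_residual_matrix(oncurve, fits, spec)
  expect_lt(max(abs(rm$R)), 1e-12)
})

test_that("the residual matrix composes per-feature residual calls", {
  g <- scored_fixture()
  spec <- small_spec()
  fits <- fit_normative_set(g$cohort, spec, fast_smoother())
  rm <- suppressWarnings(assemble_residual_matrix(g$cohort, fits, spec))
  sc <- cohort_scans(g$cohort, spec)
  for (f in spec$feature[c(1, 5)]) {
    d <- tibble::tibble(age = sc$info$age, coil = sc$info$coil,
                        tmi = sc$info$tmi, value = sc$Y[, f])
    expect_equal(rm$R[, f],
                 suppressWarnings(marginal_residuals(fits[[f]], d)),
                 tolerance = 1e-12)
  }
  expect_error(assemble_residual_matrix(g$cohort, fits[-1], spec), "gcc.FA")
})

test_that("permuting the feature order permutes columns but leaves distances unchanged", {
  g <- scored_fixture()
  spec <- small_spec()
  perm <- feature_spec(rev(spec$roi), rev(spec$parameter))
  fits <- fit_normative_set(g$cohort, spec, fast_smoother())
  rm1 <- suppressWarnings(assemble_residual_matrix(g$cohort, fits, spec,
                                                   groups = "ASD"))
  rm2 <- suppressWarnings(assemble_residual_matrix(g$cohort, fits, perm,
                                                   groups = "ASD"))
  expect_equal(rm2$R[, spec$feature], rm1$R[, spec$feature])
  tdc1 <- suppressWarnings(assemble_residual_matrix(g$cohort, fits, spec,
                                                    groups = "TDC"))
  tdc2 <- suppressWarnings(assemble_residual_matrix(g$cohort, fits, perm,
                                                    groups = "TDC"))
  d1 <- mahalanobis_distance(rm1$R, estimate_covariance(tdc1$R))
  d2 <- mahalanobis_distance(rm2$R, estimate_covariance(tdc2$R))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("adding an aligned constant vector increases distances under identity covariance", {
  withr::with_seed(31, {
    m <- 4
    X <- matrix(rnorm(30 * m), ncol = m)
    X <- X[rowSums(X) >= 0, , drop = FALSE] # nonnegative dot product with c
    S <- covariance_model(diag(m))
    d0 <- mahalanobis_distance(X, S)
    d1 <- mahalanobis_distance(X + 1, S)
    expect_true(all(d1 > d0))
  })
})

test_that("standard scores normalize residuals by the fit residual SD", {
  g <- scored_fixture()
  spec <- small_spec()
  fit <- fit_normative(g$cohort, feature = c("gcc", "FA"), fast_smoother())
  d <- tibble::tibble(age = c(10, 20), coil = "pre", tmi = 0.5)
  d$value <- predict_mean(fit, d$age, d$coil, d$tmi) +
    c(-2, -2) * fit$sigma_resid
  ss <- standard_scores(fit, d)
  expect_equal(ss$per_scan, c(-2, -2), tolerance = 1e-10)
  expect_equal(ss$aggregate_signed, -2, tolerance = 1e-10)
  expect_equal(ss$aggregate_abs, 2, tolerance = 1e-10)

  d$value <- predict_mean(fit, d$age, d$coil, d$tmi) +
    c(1, 3) * fit$sigma_resid
  ss2 <- standard_scores(fit, d)
  expect_equal(ss2$aggregate_signed, 2, tolerance = 1e-10)

  fit0 <- fit
  fit0$sigma_resid <- 1e-15
  expect_error(standard_scores(fit0, d), "degenerate")
})

test_that("LOO scoring yields exactly one entry per TDC subject", {
  g <- scored_fixture()
  spec <- small_spec()
  res <- suppressWarnings(
    loo_tdc_deviations(g$cohort, spec, fast_smoother()))
  n_tdc <- dplyr::n_distinct(g$cohort$subject_id[g$cohort$group == "TDC"])
  expect_equal(nrow(res$subjects), n_tdc)
  expect_equal(sort(unique(res$subjects$subject_id)),
               sort(unique(g$cohort$subject_id[g$cohort$group == "TDC"])))
  expect_true(all(res$subjects$dm >= 0))
})

test_that("a cohort on one common curve yields zero LOO distances", {
  # every subject's values are an exact linear trend in age: any
  # leave-one-out refit reproduces it exactly and residuals vanish
  spec <- feature_spec(c("gcc", "gcc"), c("FA", "MD"))
  base <- tiny_config(spec = spec, resid_sd = 0, subject_sd = 0,
                      asd_shift = 0,
                      coil_effect = c(FA = 0, MD = 0, AD = 0, RD = 0),
                      tmi_effect = c(FA = 0, MD = 0, AD = 0, RD = 0))
  g <- generate_cohort(base, seed = 2)
  lin <- g$cohort
  slope <- ifelse(lin$parameter == "FA", 0.004, -0.004)
  icept <- ifelse(lin$parameter == "FA", 0.35, 0.95)
  lin$value <- icept + slope * lin$age
  res <- suppressWarnings(
    loo_tdc_deviations(lin, spec, fast_smoother(min_subjects = 5)))
  expect_equal(max(res$subjects$dm), 0)
})

test_that("leave-one-out distances are on average at least the in-sample distances", {
  diffs <- vapply(1:3, function(s) {
    g <- scored_fixture(seed = 300 + s)
    spec <- small_spec()
    loo <- suppressWarnings(
      score_deviations(g$cohort, spec, fast_smoother(), loo = TRUE))
    ins <- suppressWarnings(
      score_deviations(g$cohort, spec, fast_smoother(), loo = FALSE))
    mean(loo$subjects$dm[loo$subjects$group == "TDC"]) -
      mean(ins$subjects$dm[ins$subjects$group == "TDC"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("restricting the feature spec before covariance estimation equals the direct subset run", {
  g <- scored_fixture(seed = 44)
  spec <- small_spec()
  fa_spec <- feature_subset(spec, parameters = "FA")
  direct <- suppressWarnings(
    score_deviations(g$cohort, fa_spec, fast_smoother(), loo = FALSE))
  # the same features pulled out of the full spec, restricted BEFORE S
  full_fits <- fit_normative_set(g$cohort, spec, fast_smoother())
  rm_tdc <- suppressWarnings(
    assemble_residual_matrix(g$cohort, full_fits, fa_spec, groups = "TDC"))
  cov_fa <- estimate_covariance(rm_tdc$R)
  rm_asd <- suppressWarnings(
    assemble_residual_matrix(g$cohort, full_fits, fa_spec, groups = "ASD"))
  d_manual <- mahalanobis_distance(rm_asd$R, cov_fa)
  d_direct <- direct$scans$dm[direct$scans$group == "ASD"]
  expect_equal(d_manual, d_direct, tolerance = 1e-10)

  # post-hoc restriction of the ALL-preset covariance is NOT the FA preset
  rm_all <- suppressWarnings(
    assemble_residual_matrix(g$cohort, full_fits, spec, groups = "TDC"))
  cov_all <- estimate_covariance(rm_all$R)
  fa_cols <- which(spec$parameter == "FA")
  cov_post <- covariance_model(cov_all$S[fa_cols, fa_cols])
  d_post <- mahalanobis_distance(rm_asd$R, cov_post)
  expect_gt(max(abs(d_post - d_direct)), 1e-6)
})
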