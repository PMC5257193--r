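test_that("the default visit structure reproduces the study scan accounting", {
  cfg <- null_config()
  d <- sample_design(cfg, seed = 7)
  expect_equal(nrow(d), 421)
  expect_equal(sum(d$group == "ASD"), 272)
  expect_equal(sum(d$group == "TDC"), 149)
  subj <- dplyr::count(d, subject_id, group)
  expect_equal(mean(subj$n[subj$group == "ASD"]), 272 / 92)
  expect_equal(mean(subj$n[subj$group == "TDC"]), 149 / 57)
  # per-timepoint counts: 92/78/60/42 ASD and 57/48/29/15 TDC
  tp <- dplyr::count(d, group, scan_index)
  expect_equal(tp$n[tp$group == "ASD"], c(92, 78, 60, 42))
  expect_equal(tp$n[tp$group == "TDC"], c(57, 48, 29, 15))
})

test_that("within-subject ages are strictly increasing for any seed", {
  cfg <- tiny_config()
  for (s in c(1, 99, 12345)) {
    d <- sample_design(cfg, seed = s)
    ok <- tapply(d$age, d$subject_id, function(a) all(diff(a) > 0))
    expect_true(all(unlist(ok)))
  }
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- tiny_config()
  g1 <- generate_cohort(cfg, seed = 42)
  g2 <- generate_cohort(cfg, seed = 42)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$phenotypes, g2$phenotypes)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g1$cohort, p1, cfg$spec)
  write_cohort(g2$cohort, p2, cfg$spec)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  g3 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(g1$cohort$value, g3$cohort$value))
})

test_that("with all noise switched off, values equal trajectory plus covariate terms", {
  spec <- small_spec()
  cfg <- cohort_config(spec = spec, resid_sd = 0, subject_sd = 0,
                       asd_shift = 0)
  g <- generate_cohort(cfg, seed = 5)
  sc <- cohort_scans(g$cohort, spec)
  for (j in seq_len(nrow(spec))) {
    f <- spec$feature[j]
    expected <- mahanorm:::eval_trajectory(cfg$trajectory, f, sc$info$age) +
      cfg$coil_effect[f] * as.numeric(sc$info$coil == "post") +
      cfg$tmi_effect[f] * sc$info$tmi
    expect_equal(sc$Y[, f], unname(expected), tolerance = 1e-12)
  }
})

test_that("FA values respect their physical range under the default trajectories", {
  cfg <- null_config()
  g <- generate_cohort(cfg, seed = 3)
  fa <- g$cohort$value[g$cohort$parameter == "FA"]
  expect_true(all(fa >= 0 & fa <= 1))
  diffv <- g$cohort$value[g$cohort$parameter != "FA"]
  expect_true(all(diffv > 0))
})

test_that("a non-positive-definite residual correlation is rejected", {
  R <- matrix(0.5, 4, 4)
  diag(R) <- 1
  R[1, 4] <- R[4, 1] <- -0.5 # literal sketch that is not PD
  dimnames(R) <- list(dti_parameters(), dti_parameters())
  expect_error(cohort_config(spec = small_spec(), param_cor = R),
               "positive definite")
})

test_that("phenotypes follow the configured group ordering and noiseless limit", {
  cfg <- tiny_config()
  g <- generate_cohort(cfg, seed = 8)
  ph <- dplyr::inner_join(g$phenotypes, g$truth$subjects, by = "subject_id")
  expect_lt(mean(ph$fsiq[ph$group == "ASD"]), mean(ph$fsiq[ph$group == "TDC"]))
  expect_gt(mean(ph$srs_total_raw[ph$group == "ASD"]),
            mean(ph$srs_total_raw[ph$group == "TDC"]))

  # near-deterministic link: correlation approaches -1
  cfg2 <- tiny_config(phenotype_link = c(fsiq = -0.999, piq = -0.27,
                                         viq = -0.21, srs = 0.12))
  g2 <- generate_cohort(cfg2, seed = 8)
  ph2 <- dplyr::inner_join(g2$phenotypes, g2$truth$subjects, by = "subject_id")
  asd <- ph2[ph2$group == "ASD", ]
  expect_lt(cor(asd$fsiq, asd$deviation_magnitude), -0.99)
  expect_error(cohort_config(spec = small_spec(),
                             phenotype_link = c(fsiq = -1, piq = 0, viq = 0,
                                                srs = 0)),
               "phenotype_link")
})

test_that("a null phenotype link recovers a mean correlation of zero", {
  cfg <- null_config(phenotype_link = c(fsiq = 0, piq = 0, viq = 0, srs = 0))
  rs <- vapply(1:60, function(s) {
    g <- generate_cohort(cfg, seed = 4000 + s)
    ph <- dplyr::inner_join(g$phenotypes, g$truth$subjects, by = "subject_id")
    asd <- ph[ph$group == "ASD", ]
    cor(asd$fsiq, asd$deviation_magnitude)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("scan-level feature vectors are group-exchangeable under the null generator", {
  # equal TMI distributions and a scan-count-matched visit structure, so the
  # marginal scan-age mix (and hence the value distribution) is identical
  cfg <- null_config(
    tmi_asd_ratio = 1,
    visit_structure = tibble::tibble(
      n_subjects = c(20L, 10L, 20L, 10L),
      n_scans = c(3L, 1L, 3L, 1L),
      group = c("ASD", "ASD", "TDC", "TDC")))
  ps <- vapply(1:30, function(s) {
    g <- generate_cohort(cfg, seed = 900 + s)
    sc <- cohort_scans(g$cohort, cfg$spec)
    # KS test on the first feature's values, ASD vs TDC scans
    suppressWarnings(stats::ks.test(
      sc$Y[sc$info$group == "ASD", 1], sc$Y[sc$info$group == "TDC", 1])$p.value)
  }, numeric(1))
  # nominal behavior: roughly uniform p-values, not concentrated near 0
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.25)
})

test_that("a strong configured effect separates the groups in nearly all replicates", {
  cfg <- effect_config(shift = 0.8, scale = 2)
  wins <- vapply(1:25, function(s) {
    g <- generate_cohort(cfg, seed = 2100 + s)
    dv <- suppressWarnings(
      score_deviations(g$cohort, cfg$spec, fast_smoother(), loo = FALSE))
    mean(dv$subjects$dm[dv$subjects$group == "ASD"]) >
      mean(dv$subjects$dm[dv$subjects$group == "TDC"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
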