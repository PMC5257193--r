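# shared fixtures: all synthetic, built in code at test time

# reduced 8-feature spec (2 ROIs x 4 parameters) for fast whole-pipeline runs
small_spec <- function() default_feature_spec(rois = c("gcc", "plic_l"))

# small balanced cohort config for unit tests (fast, still longitudinal)
tiny_config <- function(spec = small_spec(), ...) {
  cohort_config(
    spec = spec,
    visit_structure = tibble::tibble(
      n_subjects = c(8L, 4L, 10L, 4L),
      n_scans = c(3L, 1L, 3L, 1L),
      group = c("ASD", "ASD", "TDC", "TDC")),
    ...)
}

# paper-style design at reduced feature count
null_config <- function(spec = small_spec(), ...) {
  cohort_config(spec = spec, asd_shift = 0, asd_scale = 1, ...)
}

effect_config <- function(spec = small_spec(), shift = 0.8, scale = 2, ...) {
  cohort_config(spec = spec, asd_shift = shift, asd_scale = scale, ...)
}

# hand-built two-subject, two-feature long cohort
toy_cohort <- function() {
  spec <- feature_spec(c("gcc", "gcc"), c("FA", "MD"))
  rows <- tidyr::expand_grid(
    tibble::tibble(subject_id = c("A1", "A1", "B1"),
                   group = c("ASD", "ASD", "TDC"),
                   scan_index = c(1L, 2L, 1L),
                   age = c(10, 12.5, 8),
                   coil = c("pre", "post", "pre"),
                   tmi = c(0.5, 0.8, 0.4)),
    tibble::tibble(roi = "gcc", parameter = c("FA", "MD")))
  rows$value <- c(0.45, 0.80, 0.48, 0.78, 0.40, 0.85)
  list(cohort = rows, spec = spec)
}

# a fast smoother configuration for repeated fitting in simulations
fast_smoother <- function(...) {
  smoother_config(lambda_grid = 10^seq(-2, 6, length.out = 9), ...)
}
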