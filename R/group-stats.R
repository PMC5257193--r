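#' Compare two groups' deviation distributions in mean and variance
#'
#' Mean difference by a two-sample t-test (Student pooled-variance by
#' default, Welch optional) and variability by the variance-ratio F test
#' `F = s_a^2 / s_b^2` with `(n_a - 1, n_b - 1)` degrees of freedom and a
#' two-sided p-value. Group a is conventionally the clinical group, so
#' positive t and F > 1 mean "increased and more variable".
#'
#' @param group_a,group_b Numeric samples (>= 2 values each).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return One-row tibble with t/F statistics, dfs, p-values and group
#'   summaries.
#' @export
two_sample_mean_variance <- function(group_a, group_b,
                                     variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = variant == "student")
  ft <- stats::var.test(group_a, group_b)
  tibble::tibble(
    t_stat = unname(tt$statistic), t_df = unname(tt$parameter),
    t_p = tt$p.value,
    f_stat = unname(ft$statistic),
    f_df1 = unname(ft$parameter[1]), f_df2 = unname(ft$parameter[2]),
    f_p = ft$p.value,
    mean_a = mean(group_a), mean_b = mean(group_b),
    sd_a = stats::sd(group_a), sd_b = stats::sd(group_b),
    n_a = length(group_a), n_b = length(group_b))
}

#' Fractions of clinical subjects exceeding reference thresholds
#'
#' The fraction of ASD subject-level distances strictly greater than the
#' TDC mean, and strictly greater than the TDC mean plus two TDC standard
#' deviations.
#'
#' @param asd Numeric vector of ASD subject distances (non-empty).
#' @param tdc Numeric vector of TDC subject distances (>= 2 values).
#' @return One-row tibble: `frac_above_mean`, `frac_above_mean_plus_2sd`,
#'   `tdc_mean`, `tdc_sd`, `n_asd`.
#' @export
exceedance_fractions <- function(asd, tdc) {
  if (length(asd) == 0) stop("ASD distance list is empty", call. = FALSE)
  if (length(tdc) < 2) stop("need at least 2 TDC distances", call. = FALSE)
  mu <- mean(tdc)
  sdv <- stats::sd(tdc)
  tibble::tibble(
    frac_above_mean = mean(asd > mu),
    frac_above_mean_plus_2sd = mean(asd > mu + 2 * sdv),
    tdc_mean = mu, tdc_sd = sdv, n_asd = length(asd))
}

#' Correlate subject deviations with phenotypes
#'
#' Pearson correlations (two-sided p-values) between subject-mean
#' deviation and each phenotype variable, within one diagnostic group,
#' with pairwise deletion of missing phenotype cells.
#'
#' @param subjects Tibble with `subject_id`, `group` and a deviation
#'   column.
#' @param phenotypes Phenotype tibble (`subject_id`, `fsiq`, `piq`, `viq`,
#'   `srs_total_raw`).
#' @param group Group to correlate within (default `"ASD"`).
#' @param dm_col Name of the deviation column (default `"dm"`).
#' @param variables Phenotype columns to use.
#' @return Tibble: `variable`, `r`, `n`, `p`. Variables with fewer than 3
#'   complete pairs yield an `NA` row with a warning.
#' @export
phenotype_correlations <- function(subjects, phenotypes, group = "ASD",
                                   dm_col = "dm",
                                   variables = c("fsiq", "piq", "viq",
                                                 "srs_total_raw")) {
  d <- dplyr::inner_join(subjects[subjects$group == group, , drop = FALSE],
                         phenotypes, by = "subject_id")
  rows <- lapply(variables, function(v) {
    ok <- stats::complete.cases(d[[dm_col]], d[[v]])
    if (sum(ok) < 3) {
      warning("insufficient complete pairs for ", v, " (", sum(ok), " < 3)",
              call. = FALSE)
      return(tibble::tibble(variable = v, r = NA_real_, n = sum(ok),
                            p = NA_real_))
    }
    ct <- stats::cor.test(d[[dm_col]][ok], d[[v]][ok])
    tibble::tibble(variable = v, r = unname(ct$estimate), n = sum(ok),
                   p = ct$p.value)
  })
  dplyr::bind_rows(rows)
}
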