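#' @importFrom rlang .data
NULL

cohort_columns <- c("subject_id", "group", "scan_index", "age",
                    "coil", "tmi", "roi", "parameter", "value")

#' Read a longitudinal cohort from a tidy CSV
#'
#' The canonical interchange format is long: one row per
#' (scan, ROI, parameter) measurement with columns `subject_id`, `group`,
#' `scan_index`, `age`, `coil`, `tmi`, `roi`, `parameter`, `value`. Extra
#' columns (e.g. a sedation flag) are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @param spec A [feature_spec()]; every scan must carry exactly one value
#'   for every feature in the spec.
#' @return A cohort tibble (long format) restricted to the spec's features.
#' @export
read_cohort <- function(path, spec = default_feature_spec()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  # base read.csv: correctly-rounded double parsing, so write -> read is the
  # exact identity on the shortest-round-trip decimals the writer emits
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(cohort_columns, names(d))
  if (length(missing) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- dplyr::mutate(d,
    subject_id = as.character(.data$subject_id),
    group = as.character(.data$group),
    scan_index = as.integer(.data$scan_index),
    age = as.double(.data$age),
    coil = as.character(.data$coil),
    tmi = as.double(.data$tmi),
    roi = as.character(.data$roi),
    parameter = as.character(.data$parameter),
    value = as.double(.data$value))
  d <- dplyr::filter(d, paste(.data$roi, .data$parameter, sep = ".") %in% spec$feature)
  check_cohort_cells(d, spec)
  arrange_cohort(d, spec)
}

# one value per (subject, scan, roi, parameter) cell, covering the spec exactly
check_cohort_cells <- function(d, spec) {
  key <- paste(d$subject_id, d$scan_index, d$roi, d$parameter, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicated (subject, scan, roi, parameter) cell(s): ",
         paste(gsub("\r", "/", utils::head(dup, 5)), collapse = ", "),
         call. = FALSE)
  }
  counts <- dplyr::count(d, .data$subject_id, .data$scan_index)
  short <- counts[counts$n != nrow(spec), , drop = FALSE]
  if (nrow(short) > 0) {
    stop("scan(s) not covering the feature spec (expected ", nrow(spec),
         " cells): ",
         paste(utils::head(paste0(short$subject_id, "/scan", short$scan_index,
                                  " has ", short$n), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(d)
}

arrange_cohort <- function(d, spec) {
  ord <- order(d$subject_id, d$scan_index,
               match(paste(d$roi, d$parameter, sep = "."), spec$feature))
  tibble::as_tibble(d[ord, , drop = FALSE])
}

#' Write a cohort to a tidy CSV
#'
#' Rows are emitted in deterministic order (subject, scan index, feature
#' order), so identical cohorts produce byte-identical files.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param spec A [feature_spec()] fixing the feature order.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, spec = default_feature_spec()) {
  missing <- setdiff(cohort_columns, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(arrange_cohort(cohort, spec), path, progress = FALSE)
  invisible(path)
}

#' Read a subject-level phenotype table
#'
#' Columns: `subject_id`, `fsiq`, `piq`, `viq`, `srs_total_raw`. Missing
#' cells are permitted and propagate as pairwise deletion in correlations.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per subject.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(c("subject_id", "fsiq", "piq", "viq", "srs_total_raw"), names(d))
  if (length(missing) > 0) {
    stop("phenotype file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (v in c("fsiq", "piq", "viq")) {
    bad <- !is.na(d[[v]]) & (d[[v]] < 20 | d[[v]] > 200)
    if (any(bad)) {
      warning(sum(bad), " ", v, " value(s) outside the plausibility window [20, 200]",
              call. = FALSE)
    }
  }
  dplyr::mutate(d, subject_id = as.character(.data$subject_id))
}

#' Validate a cohort against its structural invariants
#'
#' Checks the measurement ranges (ages positive, FA in \[0, 1\],
#' diffusivities positive), feature completeness against the spec, and the
#' longitudinal structure (1--4 scans per subject, consecutive scan indices
#' starting at 1, strictly increasing ages, constant group label).
#'
#' @param cohort A cohort tibble.
#' @param spec A [feature_spec()].
#' @return A tibble of issues (`subject_id`, `scan_index`, `rule`,
#'   `message`); zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort, spec = default_feature_spec()) {
  issues <- list()
  add <- function(subject, scan, rule, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      subject_id = as.character(subject), scan_index = as.integer(scan),
      rule = rule, message = msg)
  }

  bad_age <- dplyr::distinct(
    dplyr::filter(cohort, .data$age <= 0),
    .data$subject_id, .data$scan_index)
  for (i in seq_len(nrow(bad_age))) {
    add(bad_age$subject_id[i], bad_age$scan_index[i], "age_positive",
        "age must be > 0")
  }

  bad_fa <- dplyr::distinct(
    dplyr::filter(cohort, .data$parameter == "FA" &
                    (.data$value < 0 | .data$value > 1)),
    .data$subject_id, .data$scan_index, .data$roi)
  for (i in seq_len(nrow(bad_fa))) {
    add(bad_fa$subject_id[i], bad_fa$scan_index[i], "fa_range",
        paste0("FA outside [0, 1] in ", bad_fa$roi[i]))
  }

  bad_diff <- dplyr::distinct(
    dplyr::filter(cohort, .data$parameter %in% c("MD", "AD", "RD") &
                    .data$value <= 0),
    .data$subject_id, .data$scan_index, .data$roi, .data$parameter)
  for (i in seq_len(nrow(bad_diff))) {
    add(bad_diff$subject_id[i], bad_diff$scan_index[i], "diffusivity_positive",
        paste0(bad_diff$parameter[i], " must be > 0 in ", bad_diff$roi[i]))
  }

  counts <- dplyr::count(cohort, .data$subject_id, .data$scan_index)
  short <- counts[counts$n != nrow(spec), , drop = FALSE]
  for (i in seq_len(nrow(short))) {
    add(short$subject_id[i], short$scan_index[i], "feature_complete",
        paste0("scan carries ", short$n[i], " of ", nrow(spec), " features"))
  }

  per_scan <- dplyr::distinct(cohort, .data$subject_id, .data$scan_index,
                              .data$age, .data$group)
  split_sub <- split(per_scan, per_scan$subject_id)
  for (sub in names(split_sub)) {
    s <- split_sub[[sub]][order(split_sub[[sub]]$scan_index), , drop = FALSE]
    if (nrow(s) > 4) {
      add(sub, NA, "scan_count", paste0("subject has ", nrow(s), " scans (max 4)"))
    }
    if (!identical(s$scan_index, seq_len(nrow(s)))) {
      add(sub, NA, "scan_index_consecutive",
          "scan_index must be consecutive integers starting at 1")
    }
    if (nrow(s) > 1 && any(diff(s$age) <= 0)) {
      add(sub, NA, "age_increasing", "ages must be strictly increasing across scans")
    }
    if (length(unique(s$group)) > 1) {
      add(sub, NA, "group_constant", "group label must be constant within subject")
    }
  }

  if (length(issues) == 0) {
    tibble::tibble(subject_id = character(), scan_index = integer(),
                   rule = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Pivot a cohort into scan-by-feature form
#'
#' Internal workhorse representation: one row of scan metadata plus a
#' numeric matrix with one column per feature in spec order.
#'
#' @param cohort A cohort tibble.
#' @param spec A [feature_spec()].
#' @return List with `info` (tibble: subject_id, group, scan_index, age,
#'   coil, tmi) and `Y` (matrix, scans x features).
#' @export
cohort_scans <- function(cohort, spec = default_feature_spec()) {
  d <- arrange_cohort(
    dplyr::filter(cohort,
                  paste(.data$roi, .data$parameter, sep = ".") %in% spec$feature),
    spec)
  check_cohort_cells(d, spec)
  info <- dplyr::distinct(d, .data$subject_id, .data$group, .data$scan_index,
                          .data$age, .data$coil, .data$tmi)
  m <- nrow(spec)
  Y <- matrix(d$value, ncol = m, byrow = TRUE,
              dimnames = list(NULL, spec$feature))
  stopifnot(nrow(Y) == nrow(info))
  list(info = info, Y = Y)
}
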