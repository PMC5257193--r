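#' White-matter regions of interest
#'
#' The 19 atlas-defined white-matter tract regions used throughout the
#' package: genu, body and splenium of the corpus callosum, plus left/right
#' homologues of the anterior and posterior limbs of the internal capsule,
#' superior longitudinal fasciculus, corticospinal tract, uncinate
#' fasciculus, cingulum, superior fronto-occipital fasciculus and sagittal
#' stratum.
#'
#' @return Character vector of 19 ROI codes.
#' @export
wm_rois <- function() {
  c("gcc", "bcc", "scc",
    "alic_r", "alic_l", "plic_r", "plic_l",
    "slf_r", "slf_l", "cst_r", "cst_l",
    "unc_r", "unc_l", "cgc_r", "cgc_l",
    "sfo_r", "sfo_l", "ss_r", "ss_l")
}

#' DTI scalar parameters
#'
#' @return Character vector: fractional anisotropy (FA), mean diffusivity
#'   (MD), axial diffusivity (AD) and radial diffusivity (RD).
#' @export
dti_parameters <- function() c("FA", "MD", "AD", "RD")

#' Construct a feature specification
#'
#' A feature specification is the ordered list of (ROI, parameter) pairs
#' that defines the multivariate observation vector. Its order is fixed for
#' the life of a pipeline run; the number of rows is the dimensionality `m`
#' of the Mahalanobis distance.
#'
#' @param roi Character vector of region codes.
#' @param parameter Character vector (recycled against `roi`) of DTI
#'   parameters, each one of `"FA"`, `"MD"`, `"AD"`, `"RD"`.
#' @return A tibble of class `feature_spec` with columns `roi`, `parameter`
#'   and a unique `feature` label.
#' @examples
#' feature_spec(c("gcc", "gcc"), c("FA", "MD"))
#' @export
feature_spec <- function(roi, parameter) {
  d <- tibble::tibble(roi = as.character(roi),
                      parameter = as.character(parameter))
  bad <- setdiff(unique(d$parameter), dti_parameters())
  if (length(bad) > 0) {
    stop("unknown DTI parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) < 1) stop("a feature spec needs at least one feature", call. = FALSE)
  d$feature <- paste(d$roi, d$parameter, sep = ".")
  if (anyDuplicated(d$feature)) {
    stop("duplicate (roi, parameter) pairs in feature spec: ",
         paste(unique(d$feature[duplicated(d$feature)]), collapse = ", "),
         call. = FALSE)
  }
  class(d) <- c("feature_spec", class(d))
  d
}

#' Default 76-feature specification
#'
#' All 19 ROIs crossed with the four DTI parameters, parameter-major so the
#' FA block comes first (m = 76 for the full set).
#'
#' @param parameters DTI parameters to include.
#' @param rois ROI codes to include.
#' @return A [feature_spec()].
#' @export
default_feature_spec <- function(parameters = dti_parameters(), rois = wm_rois()) {
  grid <- tidyr::expand_grid(parameter = parameters, roi = rois)
  feature_spec(grid$roi, grid$parameter)
}

#' Restrict a feature specification
#'
#' Restriction preserves the relative order of the retained features, so a
#' subset pipeline is exactly the full pipeline run on fewer columns.
#'
#' @param spec A [feature_spec()].
#' @param parameters,rois Optional filters; `NULL` keeps everything.
#' @return A [feature_spec()].
#' @export
feature_subset <- function(spec, parameters = NULL, rois = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  keep <- rep(TRUE, nrow(spec))
  if (!is.null(parameters)) keep <- keep & spec$parameter %in% parameters
  if (!is.null(rois)) keep <- keep & spec$roi %in% rois
  if (!any(keep)) stop("feature subset is empty", call. = FALSE)
  feature_spec(spec$roi[keep], spec$parameter[keep])
}

#' Standard feature-set presets
#'
#' The analysis presets used throughout: the full multivariate set (`ALL`),
#' each DTI parameter separately (`FA`, `MD`, `AD`, `RD`) and the commonly
#' reported `FA_MD` combination.
#'
#' @param spec Base [feature_spec()] to restrict.
#' @return Named list of [feature_spec()] objects.
#' @export
feature_presets <- function(spec = default_feature_spec()) {
  pars <- intersect(dti_parameters(), unique(spec$parameter))
  out <- c(
    list(ALL = spec),
    stats::setNames(lapply(pars, function(p) feature_subset(spec, parameters = p)), pars)
  )
  if (all(c("FA", "MD") %in% pars)) {
    out$FA_MD <- feature_subset(spec, parameters = c("FA", "MD"))
  }
  out
}
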