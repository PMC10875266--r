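#' Preprocessing: filtering, log transformation, between-sample centering
#'
#' Standard first steps of both the abundance (DPA) and usage (DPU) workflows.
#' No imputation is performed anywhere: all statistics are computed on
#' observed entries only.
#'
#' @name preprocess
NULL

#' Filter features by minimum number of observed samples
#'
#' Peptidoforms must be measured in at least `min_samples` samples or they are
#' removed. The threshold is global by default; set `per_condition` to demand
#' it within every condition level instead.
#'
#' @param assay An `intensity_assay`.
#' @param min_samples Minimum number of non-missing entries (default 2).
#' @param per_condition Optional factor/character vector over samples; when
#'   given, the threshold must hold within each level.
#' @return The filtered assay. Idempotent.
#' @export
filter_min_observed <- function(assay, min_samples = 2L, per_condition = NULL) {
  stopifnot(inherits(assay, "intensity_assay"), min_samples >= 1L)
  obs <- !is.na(assay$values)
  if (is.null(per_condition)) {
    keep <- rowSums(obs) >= min_samples
  } else {
    stopifnot(length(per_condition) == ncol(assay$values))
    counts <- vapply(split(seq_len(ncol(obs)), per_condition),
                     function(j) rowSums(obs[, j, drop = FALSE]),
                     numeric(nrow(obs)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
    keep <- apply(counts >= min_samples, 1L, all)
  }
  subset_features(assay, unname(keep))
}

#' Remove decoy and contaminant features
#'
#' @param assay An `intensity_assay`. If the flag columns are absent the assay
#'   is returned unchanged with a warning.
#' @return The filtered assay.
#' @export
remove_flagged <- function(assay) {
  stopifnot(inherits(assay, "intensity_assay"))
  have <- c("is_decoy", "is_contaminant") %in% names(assay$fdata)
  if (!any(have)) {
    warning("no decoy/contaminant flags present; assay unchanged")
    return(assay)
  }
  bad <- rep(FALSE, nrow(assay$values))
  if (have[1]) bad <- bad | isTRUE_vec(assay$fdata$is_decoy)
  if (have[2]) bad <- bad | isTRUE_vec(assay$fdata$is_contaminant)
  subset_features(assay, !bad)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Log2-transform raw intensities
#'
#' @param assay An `intensity_assay` with `scale_tag = "raw"`; values must be
#'   positive or missing (zeros are already coerced to missing on ingest).
#' @return The assay on log2 scale.
#' @export
log2_transform <- function(assay) {
  stopifnot(inherits(assay, "intensity_assay"))
  if (assay$scale_tag != "raw")
    stop("assay is already on scale '", assay$scale_tag,
         "'; log2_transform expects 'raw'")
  if (any(assay$values <= 0, na.rm = TRUE))
    stop("non-positive intensities cannot be log-transformed")
  assay$values <- log2(assay$values)
  assay$scale_tag <- "log2"
  assay
}

#' Center sample columns by their median or mean
#'
#' Between-sample normalization for the abundance workflow: every sample's
#' observed values are shifted so their median (or mean) is zero. Within-sample
#' differences between features are untouched. Idempotent per method.
#'
#' @param assay An `intensity_assay` on log2 scale.
#' @param method `"median"` (default) or `"mean"`.
#' @return The centered assay, tagged `"log2-centered"`.
#' @export
center_columns <- function(assay, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(assay, "intensity_assay"))
  if (!assay$scale_tag %in% c("log2", "log2-centered"))
    stop("centering expects a log2-scale assay, got '", assay$scale_tag, "'")
  stat <- if (method == "median") {
    apply(assay$values, 2L, stats::median, na.rm = TRUE)
  } else {
    colMeans(assay$values, na.rm = TRUE)
  }
  if (any(is.na(stat)))
    stop("sample(s) with all-missing values: ",
         paste(colnames(assay$values)[is.na(stat)], collapse = ", "))
  assay$values <- sweep(assay$values, 2L, stat, "-")
  assay$scale_tag <- "log2-centered"
  assay
}
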