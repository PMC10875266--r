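#' Multi-level linked-assay containers for peptidoform and PTM data
#'
#' A `ptm_experiment` stores a named collection of intensity assays (matrices
#' of log2 intensities with per-feature annotations), feature-level links
#' between assays, and one sample-annotation table. Preprocessing steps never
#' overwrite an assay: each step appends a new, linked assay so the raw input
#' is always recoverable and every derived matrix can be traced back to its
#' origin.
#'
#' @name core-data
NULL

#' Construct an intensity assay
#'
#' An intensity assay is a features x samples matrix together with per-feature
#' annotations and a scale tag recording where in the workflow the values sit.
#' Missing measurements are `NA`, never zero; sample columns are reordered to
#' match the annotation order of the experiment on ingest.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Must
#'   carry rownames (feature ids) and colnames (sample ids).
#' @param fdata Data frame of feature annotations, one row per feature, in the
#'   row order of `values`. Recognised columns: `sequence`, `parent_protein`,
#'   `modifications` (a list column of data frames with `mod_name`, `residue`,
#'   `peptide_site`, `protein_site`), `is_decoy`, `is_contaminant`. A
#'   `feature_id` column is added from the rownames.
#' @param scale_tag One of `"raw"`, `"log2"`, `"log2-centered"`,
#'   `"log2-usage"`. Transitions only move forward along the workflow.
#'
#' @return An object of class `intensity_assay`.
#' @export
intensity_assay <- function(values, fdata = NULL,
                            scale_tag = c("raw", "log2", "log2-centered",
                                          "log2-usage")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (features) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids in assay")
  if (is.null(fdata)) {
    fdata <- data.frame(feature_id = rownames(values),
                        stringsAsFactors = FALSE)
  } else {
    if (nrow(fdata) != nrow(values))
      stop("'fdata' must have one row per feature")
    fdata$feature_id <- rownames(values)
  }
  rownames(fdata) <- rownames(values)
  structure(list(values = values, fdata = fdata, scale_tag = scale_tag),
            class = "intensity_assay")
}

#' @export
dim.intensity_assay <- function(x) dim(x$values)

#' @export
print.intensity_assay <- function(x, ...) {
  cat(sprintf("<intensity_assay> %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' Feature identifiers of an assay
#' @param assay An `intensity_assay`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(assay) rownames(assay$values)

#' Sample identifiers of an assay
#' @param assay An `intensity_assay`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(assay) colnames(assay$values)

scale_rank <- c(raw = 1L, log2 = 2L, "log2-centered" = 3L, "log2-usage" = 4L)

#' Construct a feature link between two assays
#'
#' Links record how features of a derived ("parent", higher-level) assay are
#' built from features of a source ("child", lower-level) assay, e.g. which
#' peptidoforms contribute to a PTM site. The mapping is many-to-many: a
#' peptidoform carrying several modifications belongs to several PTM parents.
#'
#' @param parent_assay,child_assay Assay names within the experiment.
#' @param map Data frame with columns `child_id` and `parent_id`.
#' @return An object of class `feature_link`.
#' @export
feature_link <- function(parent_assay, child_assay, map) {
  stopifnot(is.data.frame(map), all(c("child_id", "parent_id") %in% names(map)))
  structure(list(parent_assay = parent_assay, child_assay = child_assay,
                 map = map[, c("child_id", "parent_id")]),
            class = "feature_link")
}

#' Construct a multi-level PTM experiment
#'
#' @param samples Data frame of sample annotations with a unique `sample_id`
#'   column plus arbitrary design columns (`condition`, `biorepeat`, ...).
#' @param assays Optional named list of `intensity_assay` objects; their
#'   columns must be a subset of `samples$sample_id` and are reordered to the
#'   annotation order.
#' @param links Optional list of `feature_link` objects.
#' @return An object of class `ptm_experiment`.
#' @export
ptm_experiment <- function(samples, assays = list(), links = list()) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  if (anyDuplicated(samples$sample_id))
    stop("'sample_id' must be unique")
  samples$sample_id <- as.character(samples$sample_id)
  x <- structure(list(samples = samples, assays = list(), links = list()),
                 class = "ptm_experiment")
  for (nm in names(assays)) x <- add_assay(x, nm, assays[[nm]])
  for (l in links) x$links[[length(x$links) + 1L]] <- l
  x
}

#' @export
print.ptm_experiment <- function(x, ...) {
  cat(sprintf("<ptm_experiment> %d samples, %d assay(s), %d link(s)\n",
              nrow(x$samples), length(x$assays), length(x$links)))
  for (nm in names(x$assays)) {
    a <- x$assays[[nm]]
    cat(sprintf("  $%s: %d x %d [%s]\n", nm, nrow(a$values), ncol(a$values),
                a$scale_tag))
  }
  invisible(x)
}

#' Add an assay (and optionally a link) to an experiment
#'
#' The returned experiment holds one more assay; all previously stored assays
#' are untouched. Sample columns of the new assay are canonicalized to the
#' sample-annotation order.
#'
#' @param x A `ptm_experiment`.
#' @param name Assay name; must not already be present.
#' @param assay An `intensity_assay`.
#' @param link Optional `feature_link` whose endpoints must exist (the assay
#'   being added counts as existing).
#' @return The extended `ptm_experiment`.
#' @export
add_assay <- function(x, name, assay, link = NULL) {
  stopifnot(inherits(x, "ptm_experiment"), inherits(assay, "intensity_assay"))
  if (name %in% names(x$assays))
    stop(sprintf("assay '%s' already present", name))
  extra <- setdiff(sample_ids(assay), x$samples$sample_id)
  if (length(extra))
    stop("assay contains samples absent from the annotation: ",
         paste(extra, collapse = ", "))
  ord <- intersect(x$samples$sample_id, sample_ids(assay))
  assay$values <- assay$values[, ord, drop = FALSE]
  x$assays[[name]] <- assay
  if (!is.null(link)) {
    stopifnot(inherits(link, "feature_link"))
    for (end in c(link$parent_assay, link$child_assay))
      if (!end %in% names(x$assays))
        stop(sprintf("link endpoint '%s' is not an assay", end))
    pids <- feature_ids(x$assays[[link$parent_assay]])
    cids <- feature_ids(x$assays[[link$child_assay]])
    if (!all(link$map$parent_id %in% pids) || !all(link$map$child_id %in% cids))
      stop("link mapping references unknown feature ids")
    x$links[[length(x$links) + 1L]] <- link
  }
  x
}

#' Retrieve an assay by name
#' @param x A `ptm_experiment`.
#' @param name Assay name.
#' @return The `intensity_assay`.
#' @export
get_assay <- function(x, name) {
  if (!name %in% names(x$assays)) stop(sprintf("no assay '%s'", name))
  x$assays[[name]]
}

#' Traverse a feature link
#'
#' @param x A `ptm_experiment`.
#' @param from,to Assay names; a link between them (either direction) must
#'   exist.
#' @param ids Feature ids in the `from` assay.
#' @return Character vector of linked feature ids in the `to` assay.
#' @export
linked_features <- function(x, from, to, ids) {
  for (l in x$links) {
    if (l$parent_assay == to && l$child_assay == from)
      return(unique(l$map$parent_id[l$map$child_id %in% ids]))
    if (l$parent_assay == from && l$child_assay == to)
      return(unique(l$map$child_id[l$map$parent_id %in% ids]))
  }
  stop(sprintf("no link between '%s' and '%s'", from, to))
}

#' Subset an assay to a set of samples
#'
#' @param assay An `intensity_assay`.
#' @param ids Sample ids to keep, in the desired order.
#' @return The column-subsetted assay.
#' @export
subset_samples <- function(assay, ids) {
  stopifnot(inherits(assay, "intensity_assay"),
            all(ids %in% sample_ids(assay)))
  assay$values <- assay$values[, ids, drop = FALSE]
  assay
}

#' Subset an assay by a feature predicate
#'
#' @param assay An `intensity_assay`.
#' @param predicate Function taking the feature-annotation data frame and
#'   returning a logical vector (NA treated as FALSE), or a logical/character
#'   vector of features to keep.
#' @return The subsetted assay; columns unchanged. An empty result is allowed.
#' @export
subset_features <- function(assay, predicate) {
  stopifnot(inherits(assay, "intensity_assay"))
  keep <- if (is.function(predicate)) predicate(assay$fdata) else predicate
  if (is.character(keep)) keep <- rownames(assay$values) %in% keep
  keep[is.na(keep)] <- FALSE
  assay$values <- assay$values[keep, , drop = FALSE]
  assay$fdata <- assay$fdata[keep, , drop = FALSE]
  assay
}
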