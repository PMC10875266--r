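#' Robust summarization to protein and PTM level, and usage normalization
#'
#' Several peptidoform rows are condensed into one profile per sample by
#' fitting the additive two-way model
#' \deqn{y_{fs} = \mathrm{sample}_s + \mathrm{feature}_f + \varepsilon_{fs}}
#' by iteratively reweighted least squares with Huber weights, with the
#' feature effects constrained to sum to zero so the sample effect is directly
#' interpretable as the consensus intensity profile. The same engine serves
#' protein summarization (for usage normalization) and PTM-site summarization.
#'
#' Usage normalization subtracts the summarized parent-protein profile from
#' each peptidoform, \eqn{y^*_{i,p,P} = y_{i,p,P} - \mu_{i,P}}, so that
#' downstream tests ask whether a peptidoform/PTM changes *relative to its
#' protein* rather than in absolute abundance.
#'
#' @name summarize
NULL

#' Robust two-way summary of a features x samples submatrix
#'
#' Fits `value ~ sample + feature` (feature effects sum to zero) by Huber
#' IRLS and returns the estimated sample effects. Missing cells are simply
#' omitted rows of the two-way design; a sample with no observed value among
#' the features gets a missing summary. The residual scale is re-estimated
#' each iteration as the MAD of the residuals; with a single feature the
#' summary is that feature's row unchanged.
#'
#' @param x Numeric matrix, contributing features in rows, samples in columns.
#' @param huber_k Huber tuning constant; 1.345 gives 95% efficiency under
#'   Gaussian errors. `Inf` reproduces the least-squares fit.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum IRLS iterations; on non-convergence the last
#'   iterate is returned with attribute `converged = FALSE`.
#' @return Named numeric vector of per-sample summaries, with attribute
#'   `converged`.
#' @export
robust_summary <- function(x, huber_k = 1.345, tol = 1e-6, max_iter = 100L) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  samples <- colnames(x)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(x)))
  out <- stats::setNames(rep(NA_real_, ncol(x)), samples)

  x <- x[rowSums(!is.na(x)) > 0L, , drop = FALSE]
  if (nrow(x) == 0L) { attr(out, "converged") <- TRUE; return(out) }
  if (nrow(x) == 1L) {
    out[] <- x[1L, ]
    attr(out, "converged") <- TRUE
    return(out)
  }

  obs <- which(!is.na(x), arr.ind = TRUE)
  y <- x[obs]
  sfac <- factor(obs[, 2L], levels = seq_len(ncol(x)))
  ffac <- factor(obs[, 1L])
  seen <- tabulate(sfac, nbins = ncol(x)) > 0L
  sfac <- droplevels(sfac)

  # sample indicators (no intercept) + sum-coded feature effects
  Xs <- stats::model.matrix(~ 0 + sfac)
  Xf <- if (nlevels(ffac) > 1L) {
    stats::model.matrix(~ ffac, contrasts.arg = list(ffac = "contr.sum"))[, -1L,
                                                                  drop = FALSE]
  } else NULL
  X <- cbind(Xs, Xf)
  ns <- ncol(Xs)

  w <- rep(1, length(y))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    r <- y - drop(X %*% b)
    if (max(abs(b - beta)) < tol) { beta <- b; converged <- TRUE; break }
    beta <- b
    if (is.infinite(huber_k)) { converged <- TRUE; break }
    s <- stats::median(abs(r)) / 0.6745
    if (s < .Machine$double.eps^0.5) { converged <- TRUE; break }
    w <- pmin(1, huber_k * s / abs(r))
  }
  coefs <- fit$coefficients[seq_len(ns)]
  coefs[is.na(coefs)] <- NA_real_
  out[seen] <- coefs
  attr(out, "converged") <- converged
  out
}

#' Summarize peptidoforms to one profile per protein
#'
#' Groups the assay's features by parent protein and applies
#' [robust_summary()] within each group. Shared peptides (several parent
#' accessions separated by `;`) are excluded by default to avoid double
#' counting; set `shared_policy = "first"` to assign them to the first listed
#' accession instead.
#'
#' @param assay Peptidoform `intensity_assay` on a log2 scale with a
#'   `parent_protein` annotation column.
#' @param shared_policy `"exclude"` (default) or `"first"`.
#' @param huber_k,tol,max_iter Passed to [robust_summary()].
#' @return An `intensity_assay` with one row per protein and an `n_children`
#'   annotation counting contributing peptidoforms.
#' @export
summarize_proteins <- function(assay, shared_policy = c("exclude", "first"),
                               huber_k = 1.345, tol = 1e-6, max_iter = 100L) {
  shared_policy <- match.arg(shared_policy)
  stopifnot(inherits(assay, "intensity_assay"),
            "parent_protein" %in% names(assay$fdata))
  prot <- assay$fdata$parent_protein
  shared <- grepl(";", prot, fixed = TRUE)
  if (any(shared)) {
    if (shared_policy == "exclude") {
      prot[shared] <- NA_character_
    } else {
      prot[shared] <- sub(";.*$", "", prot[shared])
    }
  }
  usable <- !is.na(prot) & prot != ""
  if (!all(usable))
    warning(sum(!usable), " feature(s) without usable parent protein skipped")
  groups <- split(which(usable), prot[usable])
  vals <- matrix(NA_real_, length(groups), ncol(assay$values),
                 dimnames = list(names(groups) %||% character(0),
                                 colnames(assay$values)))
  for (i in seq_along(groups)) {
    vals[i, ] <- robust_summary(assay$values[groups[[i]], , drop = FALSE],
                                huber_k = huber_k, tol = tol,
                                max_iter = max_iter)
  }
  fdata <- data.frame(parent_protein = names(groups),
                      n_children = lengths(groups),
                      stringsAsFactors = FALSE)
  intensity_assay(vals, fdata, scale_tag = assay$scale_tag)
}

#' Usage normalization: subtract the parent-protein profile
#'
#' Computes \eqn{y^* = y - \mu} per (peptidoform, sample), where \eqn{\mu} is
#' the summarized parent-protein intensity from `protein_summaries` (built
#' from a non-enriched global-profiling run where available, else from the
#' enriched data itself). Features whose protein is absent from the summaries
#' cannot be normalized and are dropped; their count and ids are attached as
#' attribute `dropped`. Missing entries stay missing: a missing \eqn{y} or
#' \eqn{\mu} yields a missing \eqn{y^*}.
#'
#' @param assay Peptidoform `intensity_assay` on a log2 scale.
#' @param protein_summaries Protein-level assay from [summarize_proteins()]
#'   (or any assay whose feature ids are protein accessions).
#' @param shared_policy How shared peptides pick their parent; see
#'   [summarize_proteins()].
#' @return The normalized assay, tagged `"log2-usage"`, with attribute
#'   `dropped` listing excluded feature ids.
#' @export
usage_normalize <- function(assay, protein_summaries,
                            shared_policy = c("exclude", "first")) {
  shared_policy <- match.arg(shared_policy)
  stopifnot(inherits(assay, "intensity_assay"),
            inherits(protein_summaries, "intensity_assay"))
  if (scale_rank[assay$scale_tag] < scale_rank["log2"])
    stop("usage normalization expects log2-scale input")
  prot <- assay$fdata$parent_protein
  shared <- grepl(";", prot, fixed = TRUE)
  prot[shared] <- if (shared_policy == "exclude") NA_character_ else
    sub(";.*$", "", prot[shared])

  have <- !is.na(prot) & prot %in% feature_ids(protein_summaries)
  dropped <- rownames(assay$values)[!have]
  out <- subset_features(assay, have)
  prot <- prot[have]
  common <- intersect(colnames(out$values), colnames(protein_summaries$values))
  mu <- protein_summaries$values[prot, common, drop = FALSE]
  out$values[, common] <- out$values[, common, drop = FALSE] - mu
  not_shared <- setdiff(colnames(out$values), common)
  if (length(not_shared)) out$values[, not_shared] <- NA_real_
  out$scale_tag <- "log2-usage"
  attr(out, "dropped") <- dropped
  out
}

#' Expand peptidoforms into PTM groups
#'
#' Builds the many-to-many link between peptidoforms and PTM sites: every
#' peptidoform appears under every PTM key it carries (a peptidoform with a
#' phospho and an oxidation belongs to both groups); unmodified peptidoforms
#' map to no PTM. Keys are protein-site based when the peptide start position
#' is annotated and fall back to `pep:`-prefixed peptide-relative sites
#' otherwise.
#'
#' @param assay Peptidoform `intensity_assay` with parsed `modifications`
#'   annotations.
#' @param assay_name Name of the peptidoform assay within the experiment.
#' @param ptm_assay_name Name the summarized PTM assay will take.
#' @param shared_policy How shared peptides pick their parent protein.
#' @return A `feature_link` with the PTM assay as parent.
#' @export
expand_to_ptm <- function(assay, assay_name = "peptidoforms",
                          ptm_assay_name = "ptm",
                          shared_policy = c("exclude", "first")) {
  shared_policy <- match.arg(shared_policy)
  stopifnot(inherits(assay, "intensity_assay"),
            "modifications" %in% names(assay$fdata))
  prot <- assay$fdata$parent_protein
  shared <- grepl(";", prot, fixed = TRUE)
  prot[shared] <- if (shared_policy == "exclude") NA_character_ else
    sub(";.*$", "", prot[shared])
  starts <- if ("peptide_start" %in% names(assay$fdata))
    assay$fdata$peptide_start else rep(NA_integer_, nrow(assay$fdata))

  child <- character(0); parent <- character(0)
  for (i in seq_len(nrow(assay$fdata))) {
    if (is.na(prot[i])) next
    mods <- assay$fdata$modifications[[i]]
    if (is.null(mods) || nrow(mods) == 0L) next
    st <- if (is.na(starts[i])) NULL else starts[i]
    keys <- vapply(seq_len(nrow(mods)), function(j)
      ptm_key(prot[i], mods$mod_name[j], mods$peptide_site[j],
              peptide_start = st, stripped = assay$fdata$sequence[i]),
      character(1))
    child <- c(child, rep(assay$fdata$feature_id[i], length(keys)))
    parent <- c(parent, keys)
  }
  feature_link(parent_assay = ptm_assay_name, child_assay = assay_name,
               map = data.frame(child_id = child, parent_id = parent,
                                stringsAsFactors = FALSE))
}

#' Summarize peptidoforms to PTM level
#'
#' Applies [robust_summary()] to the peptidoform subset of every PTM group in
#' the link. Operates on whatever scale the input assay carries: centered
#' log2 intensities for abundance (DPA) analysis, log2 usages for usage (DPU)
#' analysis. A PTM backed by a single peptidoform reproduces that
#' peptidoform's row exactly; with several parallel peptidoforms the summary
#' sits in their middle.
#'
#' @param assay Peptidoform `intensity_assay`.
#' @param link `feature_link` from [expand_to_ptm()].
#' @param huber_k,tol,max_iter Passed to [robust_summary()].
#' @return A PTM-level `intensity_assay` with `n_children` annotations.
#' @export
summarize_ptms <- function(assay, link, huber_k = 1.345, tol = 1e-6,
                           max_iter = 100L) {
  stopifnot(inherits(assay, "intensity_assay"), inherits(link, "feature_link"))
  map <- link$map[link$map$child_id %in% feature_ids(assay), , drop = FALSE]
  groups <- split(map$child_id, map$parent_id)
  vals <- matrix(NA_real_, length(groups), ncol(assay$values),
                 dimnames = list(names(groups) %||% character(0),
                                 colnames(assay$values)))
  for (i in seq_along(groups)) {
    vals[i, ] <- robust_summary(assay$values[groups[[i]], , drop = FALSE],
                                huber_k = huber_k, tol = tol,
                                max_iter = max_iter)
  }
  fdata <- data.frame(ptm = names(groups), n_children = lengths(groups),
                      stringsAsFactors = FALSE)
  intensity_assay(vals, fdata, scale_tag = assay$scale_tag)
}
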