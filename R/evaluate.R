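#' Benchmark scoring, calibration checks and plots
#'
#' Confusion metrics at a significance cutoff, tpr-fdp and ROC curves along
#' the significance ranking, Kolmogorov-Smirnov uniformity checks of mock
#' p-values, and the standard line/volcano visualizations. Here tpr is the
#' fraction of truly differential features picked up by the method, and fdp
#' the fraction of false positives among all features flagged as
#' differential. Features without a fitted model never count as discoveries;
#' in the curves they are appended after all ranked features, which makes
#' "cannot fit" visible as a final vertical rise.
#'
#' @name evaluate
NULL

truth_lookup <- function(rows, truth, truth_col) {
  stopifnot(is.data.frame(truth), truth_col %in% names(truth))
  candidates <- intersect(c("feature_id", "pepform_id", "ptm"), names(truth))
  covered <- vapply(candidates,
                    function(cc) all(rows$feature_id %in% truth[[cc]]),
                    logical(1))
  if (!any(covered))
    stop("truth table does not cover the tested features")
  key_col <- candidates[which(covered)[1]]
  idx <- match(rows$feature_id, truth[[key_col]])
  as.logical(truth[[truth_col]][idx])
}

#' Confusion metrics at a significance level
#'
#' Features with a BH-adjusted p-value at or below `alpha` are called;
#' features without a p-value (no model fit) are counted as not called.
#' Standard 2x2-table definitions; `fdp = FP / max(1, FP + TP)`.
#'
#' @param rows Inference rows (one contrast) from [test_contrasts()].
#' @param truth Truth table with a feature-id column (`ptm`, `pepform_id` or
#'   `feature_id`) and the logical truth column.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @param truth_col Name of the logical truth column, e.g.
#'   `"is_differential_usage"` for usage analyses.
#' @return Named list: `fpr`, `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `fdp`, `n_called`.
#' @export
confusion_at_alpha <- function(rows, truth, alpha = 0.05,
                               truth_col = "is_differential_usage") {
  stopifnot(nrow(rows) > 0L)
  pos <- truth_lookup(rows, truth, truth_col)
  called <- !is.na(rows$adj_pval) & rows$adj_pval <= alpha
  tp <- sum(called & pos); fp <- sum(called & !pos)
  fn <- sum(!called & pos); tn <- sum(!called & !pos)
  list(fpr = if (fp + tn > 0) fp / (fp + tn) else 0,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       accuracy = (tp + tn) / length(pos),
       fdp = fp / max(1L, fp + tp),
       n_called = tp + fp)
}

rank_rows <- function(rows) {
  has_p <- !is.na(rows$pval)
  tt <- abs(rows$t); tt[is.na(tt)] <- -Inf
  ord <- order(!has_p, rows$pval, -tt, rows$feature_id, na.last = TRUE)
  rows[ord, , drop = FALSE]
}

#' tpr-fdp curve along the significance ranking
#'
#' Features are ranked by p-value (ties broken by descending |t|, then
#' feature id); at every rank the cumulative true positive rate and false
#' discovery proportion are reported. Features without a p-value are appended
#' last. The point reached when thresholding BH-adjusted p-values at
#' `fdr_cutoff` is marked (`at_cutoff` attribute).
#'
#' @param rows Inference rows for one contrast.
#' @param truth,truth_col As in [confusion_at_alpha()].
#' @param fdr_cutoff FDR level for the marker point.
#' @return Data frame with `rank`, `feature_id`, `tpr`, `fdp`, `fpr`, and
#'   attribute `at_cutoff`.
#' @export
tpr_fdp_curve <- function(rows, truth, truth_col = "is_differential_usage",
                          fdr_cutoff = 0.05) {
  rows <- rank_rows(rows)
  pos <- truth_lookup(rows, truth, truth_col)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  out <- data.frame(rank = seq_along(pos), feature_id = rows$feature_id,
                    tpr = if (n_pos > 0) tp / n_pos else NA_real_,
                    fdp = fp / pmax(1L, tp + fp),
                    fpr = if (n_neg > 0) fp / n_neg else NA_real_,
                    stringsAsFactors = FALSE)
  n_called <- sum(!is.na(rows$adj_pval) & rows$adj_pval <= fdr_cutoff)
  attr(out, "at_cutoff") <- if (n_called > 0)
    out[n_called, c("tpr", "fdp", "fpr")] else
    data.frame(tpr = 0, fdp = 0, fpr = 0)
  out
}

#' ROC curve (tpr vs fpr) along the significance ranking
#'
#' Same ranking and conventions as [tpr_fdp_curve()] with the false positive
#' rate on the x-axis; `auc` (trapezoidal, over the ranked features) is
#' attached as an attribute.
#'
#' @inheritParams tpr_fdp_curve
#' @return Data frame of curve points with attribute `auc`.
#' @export
roc_curve <- function(rows, truth, truth_col = "is_differential_usage") {
  out <- tpr_fdp_curve(rows, truth, truth_col = truth_col)
  fpr <- c(0, out$fpr); tpr <- c(0, out$tpr)
  attr(out, "auc") <- sum(diff(fpr) * (utils::head(tpr, -1) +
                                         utils::tail(tpr, -1)) / 2)
  out
}

#' Kolmogorov-Smirnov check of p-value uniformity
#'
#' Under a true null (as in a mock relabeling analysis) p-values should be
#' uniform on (0, 1); a one-sample KS test quantifies the deviation, and
#' 20-bin histogram counts are returned for plotting.
#'
#' @param pvals Numeric vector of p-values (>= 10 values, all in `[0, 1]`).
#' @return List with `ks_statistic`, `ks_pvalue`, `histogram_bins` (counts)
#'   and `breaks`.
#' @export
pvalue_uniformity <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 10L) stop("need at least 10 p-values")
  if (any(pvals < 0 | pvals > 1)) stop("p-values outside [0, 1]")
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  breaks <- seq(0, 1, length.out = 21L)
  h <- graphics::hist(pvals, breaks = breaks, plot = FALSE)
  list(ks_statistic = unname(ks$statistic), ks_pvalue = ks$p.value,
       histogram_bins = h$counts, breaks = breaks)
}

#' Line plot of a PTM, its peptidoforms and its parent protein
#'
#' One trace per contributing peptidoform, one for the PTM summary and one
#' for the parent-protein summary, over samples. A PTM backed by a single
#' peptidoform shows the PTM trace overlapping that peptidoform exactly.
#'
#' @param x A `ptm_experiment` holding the peptidoform, PTM and protein
#'   assays.
#' @param ptm PTM feature id.
#' @param ptm_assay,pepform_assay,protein_assay Assay names.
#' @param path Optional file path (png/pdf/svg by extension); when given the
#'   figure is written there.
#' @return A ggplot object, invisibly when written to file.
#' @export
plot_lineplot <- function(x, ptm, ptm_assay = "ptm",
                          pepform_assay = "peptidoforms_processed",
                          protein_assay = "protein_summary", path = NULL) {
  pa <- get_assay(x, ptm_assay)
  if (!ptm %in% feature_ids(pa)) stop("unknown PTM feature: ", ptm)
  peps <- linked_features(x, from = ptm_assay, to = pepform_assay, ids = ptm)
  pepa <- get_assay(x, pepform_assay)
  prota <- get_assay(x, protein_assay)
  prot <- pepa$fdata$parent_protein[match(peps, feature_ids(pepa))][1]

  long <- function(mat, ids, level) {
    m <- mat[ids, , drop = FALSE]
    data.frame(feature = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), level = level,
               stringsAsFactors = FALSE)
  }
  df <- rbind(long(pepa$values, peps, "peptidoform"),
              long(pa$values, ptm, "PTM"),
              if (!is.na(prot) && prot %in% feature_ids(prota))
                long(prota$values, prot, "protein"))
  df$sample <- factor(df$sample, levels = colnames(pa$values))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                        group = .data$feature,
                                        colour = .data$level,
                                        linetype = .data$level)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 1) +
    ggplot2::labs(title = ptm, x = NULL, y = "normalized log2 intensity") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Volcano plot of an inference result
#'
#' -log10 p-value against log2 fold change; features significant at the BH
#' level `alpha` are highlighted. An empty result set yields an empty plot
#' without error.
#'
#' @param rows Inference rows for one contrast.
#' @param alpha BH significance level.
#' @param path Optional output file.
#' @return A ggplot object, invisibly when written to file.
#' @export
plot_volcano <- function(rows, alpha = 0.05, path = NULL) {
  df <- rows[!is.na(rows$pval), , drop = FALSE]
  df$significant <- !is.na(df$adj_pval) & df$adj_pval <= alpha
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                        y = -log10(.data$pval),
                                        colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey40",
                                            "TRUE" = "red3"),
                                 drop = FALSE) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
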