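#' Reading peptidoform reports and writing result tables
#'
#' Quantification output is expected in wide format: one row per unique
#' peptidoform (stripped sequence plus ordered modification string) with its
#' parent protein(s), inline modification annotation, and one intensity column
#' per sample. No search-engine-specific converters are provided; any report
#' that can be exported to delimited text in this shape is accepted.
#'
#' @name ingest
NULL

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  counts <- vapply(c("\t", ",", ";"),
                   function(d) lengths(regmatches(first, gregexpr(d, first, fixed = TRUE))),
                   integer(1))
  c("\t", ",", ";")[which.max(counts)]
}

#' Parse an inline-modified peptide sequence
#'
#' Bracket dialect: `X[Mod Name]` attaches the modification to the immediately
#' preceding residue; a leading `[Mod Name]` denotes an N-terminal modification
#' at site 0. Example: `"LPIVNFDYS[Phospho (STY)]M[Oxidation (M)]EEK"` strips
#' to `"LPIVNFDYSMEEK"` with a phospho at peptide site 9 and an oxidation at
#' site 10.
#'
#' @param x A single modified sequence string.
#' @return A list with `stripped` (the bare sequence) and `mods`, a data frame
#'   with columns `mod_name`, `residue`, `peptide_site` (1-based; 0 for
#'   N-terminal), ordered by site.
#' @export
parse_modifications <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  stripped <- character(0)
  mods <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      depth <- 1L
      j <- i
      while (depth > 0L) {
        j <- j + 1L
        if (j > n) stop("unbalanced '[' in modified sequence: ", x)
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
      }
      mod_name <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      site <- length(stripped)           # 0 when nothing precedes: N-terminal
      residue <- if (site == 0L) "" else stripped[site]
      mods[[length(mods) + 1L]] <-
        data.frame(mod_name = mod_name, residue = residue,
                   peptide_site = site, stringsAsFactors = FALSE)
      i <- j + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' in modified sequence: ", x)
    } else {
      stripped <- c(stripped, ch)
      i <- i + 1L
    }
  }
  mods <- if (length(mods)) do.call(rbind, mods) else
    data.frame(mod_name = character(0), residue = character(0),
               peptide_site = integer(0), stringsAsFactors = FALSE)
  mods <- mods[order(mods$peptide_site), , drop = FALSE]
  rownames(mods) <- NULL
  list(stripped = paste(stripped, collapse = ""), mods = mods)
}

#' Reconstruct the inline notation from a stripped sequence and modifications
#'
#' Inverse of [parse_modifications()]; used for identity checks and for
#' writing simulated reports.
#'
#' @param stripped Bare peptide sequence.
#' @param mods Data frame as returned by [parse_modifications()].
#' @return The modified sequence string.
#' @export
reconstruct_sequence <- function(stripped, mods) {
  chars <- strsplit(stripped, "", fixed = TRUE)[[1]]
  out <- character(0)
  nterm <- mods$mod_name[mods$peptide_site == 0L]
  for (m in nterm) out <- c(out, "[", m, "]")
  for (i in seq_along(chars)) {
    out <- c(out, chars[i])
    here <- mods$mod_name[mods$peptide_site == i]
    for (m in here) out <- c(out, "[", m, "]")
  }
  paste(out, collapse = "")
}

#' Canonical PTM key
#'
#' The unit of PTM-level inference is the unique (protein, modification, site)
#' combination, e.g. `"sp|P10451|OSTP_HUMAN (Phospho (STY)) 280"`. Two
#' peptidoforms covering the same protein site (missed cleavage) yield the
#' same key. When the peptide's start position within the protein is unknown,
#' the key falls back to the peptide-relative site with an explicit `pep:`
#' prefix so keys from different peptides never silently collide.
#'
#' @param protein Protein accession.
#' @param mod_name Modification name.
#' @param peptide_site 1-based site within the stripped peptide.
#' @param peptide_start Optional 1-based start of the peptide in the protein;
#'   the protein site is then `peptide_start + peptide_site - 1`.
#' @param stripped Optional stripped sequence, used only for the `pep:`
#'   fallback to keep keys peptide-specific.
#' @return A single character key.
#' @export
ptm_key <- function(protein, mod_name, peptide_site, peptide_start = NULL,
                    stripped = NULL) {
  if (!is.null(peptide_start) && !is.na(peptide_start)) {
    site <- peptide_start + peptide_site - 1L
    sprintf("%s (%s) %d", protein, mod_name, site)
  } else {
    seqtag <- if (is.null(stripped)) "" else paste0(stripped, ":")
    sprintf("%s (%s) pep:%s%d", protein, mod_name, seqtag, peptide_site)
  }
}

#' Read a wide-format peptidoform report into an experiment
#'
#' Zero and blank intensities are coerced to missing on ingest (log2 of zero
#' is undefined and PTM data are characterized by a high amount of
#' missingness, so absence is treated as "not measured", never as zero).
#' Duplicated peptidoform identities (same modified sequence and protein) are
#' an error, not a silent merge.
#'
#' @param path Delimited text file (tab, comma or semicolon; auto-detected).
#' @param design Sample-annotation data frame with a `sample_id` column; its
#'   `sample_id` values must match the intensity column names.
#' @param intensity_columns Character vector of intensity column names;
#'   defaults to `design$sample_id`.
#' @param sequence_column Column holding the inline-modified sequence.
#' @param protein_column Column holding the parent protein accession(s);
#'   multiple accessions may be separated by `;`.
#' @param start_column Optional column with the peptide's 1-based start
#'   position in the protein.
#' @param decoy_column,contaminant_column Optional logical flag columns.
#' @param already_log2 If `TRUE` the intensities are taken as log2 and the
#'   assay is tagged `"log2"`, otherwise `"raw"`.
#' @param assay_name Name under which the assay is stored.
#' @return A `ptm_experiment` with one peptidoform assay.
#' @export
read_wide_report <- function(path, design,
                             intensity_columns = design$sample_id,
                             sequence_column = "sequence",
                             protein_column = "protein",
                             start_column = NULL,
                             decoy_column = NULL,
                             contaminant_column = NULL,
                             already_log2 = FALSE,
                             assay_name = "peptidoforms") {
  delim <- detect_delim(path)
  tab <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c(sequence_column, protein_column, intensity_columns)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  parsed <- lapply(tab[[sequence_column]], parse_modifications)
  ids <- tab[[sequence_column]]           # modified sequence IS the identity
  if (anyDuplicated(ids))
    stop("duplicated peptidoform identity: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  vals <- as.matrix(tab[, intensity_columns, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[!is.na(vals) & vals == 0] <- NA    # zero intensity -> missing
  rownames(vals) <- ids

  starts <- if (!is.null(start_column)) tab[[start_column]] else
    rep(NA_integer_, nrow(tab))
  modlist <- lapply(seq_along(parsed), function(i) {
    m <- parsed[[i]]$mods
    m$protein_site <- if (is.na(starts[i])) rep(NA_integer_, nrow(m)) else
      as.integer(starts[i]) + m$peptide_site - 1L
    m
  })
  fdata <- data.frame(
    sequence = vapply(parsed, `[[`, "", "stripped"),
    parent_protein = as.character(tab[[protein_column]]),
    peptide_start = as.integer(starts),
    is_decoy = if (!is.null(decoy_column)) as.logical(tab[[decoy_column]])
               else rep(FALSE, nrow(tab)),
    is_contaminant = if (!is.null(contaminant_column))
               as.logical(tab[[contaminant_column]])
               else rep(FALSE, nrow(tab)),
    stringsAsFactors = FALSE)
  fdata$modifications <- modlist

  assay <- intensity_assay(vals, fdata,
                           scale_tag = if (already_log2) "log2" else "raw")
  x <- ptm_experiment(design)
  add_assay(x, assay_name, assay)
}

#' Write an inference result table to CSV
#'
#' The significance table carries, per feature and contrast: log2 fold change,
#' standard error, test statistic, degrees of freedom, p-value and
#' BH-adjusted p-value. Written with full double precision so a write/read
#' round trip is lossless to within float text precision.
#'
#' @param rows Data frame of inference rows as returned by [test_contrasts()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  cols <- c("feature_id", "contrast", "logFC", "se", "t", "df", "pval",
            "adj_pval")
  stopifnot(all(cols %in% names(rows)))
  utils::write.csv(format(rows[, cols], digits = 17, trim = TRUE,
                          scientific = NA),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path CSV path.
#' @return Data frame of inference rows.
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("logFC", "se", "t", "df", "pval", "adj_pval"))
    tab[[col]] <- as.numeric(tab[[col]])
  tab
}
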