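#' Synthetic two-level benchmark data, spike-in emulation and mock relabeling
#'
#' Generators reproducing the statistical structure of the benchmark used to
#' validate the workflows: an enriched PTM peptidoform assay linked to a
#' global-profiling protein assay, with known differential/confounded truth;
#' a spike-in design with known adjusted and unadjusted log2 fold changes;
#' and random relabeling of single-condition samples for null calibration.
#' Every generator is fully reproducible from its seed and leaves the global
#' RNG stream untouched.
#'
#' @name simulate
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Benchmark scenario configuration
#'
#' Defaults encode the benchmark conditions: 1000 PTMs, 10 peptidoforms per
#' PTM, half of the PTMs differentially abundant, 250 of those confounded
#' with a parent-protein change, intensity noise SD 0.2 (low-variance
#' setting) or 0.3, and — for the scenario with missingness — entries masked
#' completely at random at rate 0.2.
#'
#' @param n_ptms Number of simulated PTMs (one per parent protein).
#' @param n_pepforms_per_ptm Distinct peptidoforms carrying each PTM.
#' @param n_conditions Number of conditions (2, 3 or 4).
#' @param n_replicates Replicates per condition.
#' @param noise_sd SD of the i.i.d. Gaussian intensity noise (log2 scale).
#' @param effect_size Magnitude of the differential log2 fold changes.
#' @param n_confounded Number of differential PTMs whose change is driven by
#'   the parent protein (no usage effect); must not exceed `n_ptms/2`.
#'   Defaults to `n_ptms/4` (250 at the default size).
#' @param missing_rate Missingness rate (scenario 2 only).
#' @param missing_mechanism `"mcar"` (default) or `"mnar"`
#'   (logistic-in-intensity: lower intensities more likely missing).
#' @param seed Integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_ptms = 1000L, n_pepforms_per_ptm = 10L,
                            n_conditions = 2L, n_replicates = 2L,
                            noise_sd = 0.2, effect_size = 1,
                            n_confounded = NULL, missing_rate = 0.2,
                            missing_mechanism = c("mcar", "mnar"),
                            seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  n_diff <- n_ptms %/% 2L
  if (is.null(n_confounded)) n_confounded <- n_ptms %/% 4L
  stopifnot(n_conditions %in% 2:4, n_replicates >= 2L,
            n_confounded <= n_diff, noise_sd > 0)
  structure(list(n_ptms = as.integer(n_ptms),
                 n_pepforms_per_ptm = as.integer(n_pepforms_per_ptm),
                 n_conditions = as.integer(n_conditions),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, effect_size = effect_size,
                 n_differential = n_diff,
                 n_confounded = as.integer(n_confounded),
                 missing_rate = missing_rate,
                 missing_mechanism = missing_mechanism,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate one two-level benchmark dataset
#'
#' Generative model, per parent protein (one PTM per protein): a baseline
#' log2 intensity `Normal(25, 2)`; per peptidoform a fixed offset
#' `Normal(0, 1)`; a protein condition effect added to all its peptidoforms
#' *and* to the protein's global-profiling row; a PTM usage effect added only
#' to the modified (enriched) peptidoforms; i.i.d. Gaussian noise with
#' `noise_sd`. Half the PTMs are differentially abundant: `n_confounded` of
#' them are confounded (the parent protein changes, the usage does not) and
#' the rest carry a pure usage effect; signs are balanced. Differential-
#' abundance truth and differential-usage truth are therefore distinct
#' columns of the truth table. Scenario 1 has no missing entries; scenario 2
#' masks entries of both assays at `missing_rate`.
#'
#' @param cfg A [scenario_config()].
#' @param scenario 1 (complete data) or 2 (with missingness).
#' @return List with `enriched` (peptidoform `intensity_assay`, raw log2),
#'   `global` (protein-level assay), `design` (sample annotation) and
#'   `truth` (list of `ptms` and `peptidoforms` tables plus the config).
#' @export
simulate_scenario <- function(cfg = scenario_config(), scenario = 1L) {
  stopifnot(scenario %in% c(1L, 2L))
  with_seed(cfg$seed, {
    nP <- cfg$n_ptms
    k <- cfg$n_pepforms_per_ptm
    conds <- paste0("cond", seq_len(cfg$n_conditions))
    design <- data.frame(
      sample_id = paste0(rep(conds, each = cfg$n_replicates), "_r",
                         rep(seq_len(cfg$n_replicates), cfg$n_conditions)),
      condition = rep(conds, each = cfg$n_replicates),
      stringsAsFactors = FALSE)
    ns <- nrow(design)
    treated <- design$condition != conds[1]   # effects apply vs condition 1

    proteins <- sprintf("PROT%04d", seq_len(nP))
    site <- 50L
    mod <- "ModX"
    ptm_ids <- sprintf("%s (%s) %d", proteins, mod, site)

    # truth assignment: exact counts, drawn without replacement
    idx <- sample.int(nP)
    diff_idx <- idx[seq_len(cfg$n_differential)]
    conf_idx <- diff_idx[seq_len(cfg$n_confounded)]
    pure_idx <- setdiff(diff_idx, conf_idx)
    signs <- function(ix) {
      s <- rep(c(1, -1), length.out = length(ix))
      stats::setNames(s[sample.int(length(ix))], ix)
    }
    usage_fc <- protein_fc <- rep(0, nP)
    if (length(pure_idx))
      usage_fc[pure_idx] <- cfg$effect_size * signs(pure_idx)
    if (length(conf_idx))
      protein_fc[conf_idx] <- cfg$effect_size * signs(conf_idx)

    baseline <- stats::rnorm(nP, 25, 2)
    offsets <- matrix(stats::rnorm(nP * k, 0, 1), nP, k)

    pep_protein <- rep(proteins, each = k)
    pep_ptm <- rep(ptm_ids, each = k)
    pep_ids <- sprintf("%s_pep%02d", pep_protein, rep(seq_len(k), nP))
    pep_base <- rep(baseline, each = k) + as.vector(t(offsets))

    eff_pep <- rep(usage_fc + protein_fc, each = k)
    mean_mat <- outer(pep_base, rep(0, ns), "+") +
      outer(eff_pep, as.numeric(treated), "*")
    vals <- mean_mat + stats::rnorm(length(mean_mat), 0, cfg$noise_sd)
    dimnames(vals) <- list(pep_ids, design$sample_id)

    seqs <- vapply(seq_along(pep_ids), function(i)
      paste(c("S", sample(LETTERS[-c(2, 10, 15, 21, 24, 26)], 9,
                          replace = TRUE)), collapse = ""), character(1))
    mods <- lapply(seq_along(pep_ids), function(i)
      data.frame(mod_name = mod, residue = "S", peptide_site = 1L,
                 protein_site = site, stringsAsFactors = FALSE))
    fdata <- data.frame(sequence = seqs, parent_protein = pep_protein,
                        peptide_start = site, is_decoy = FALSE,
                        is_contaminant = FALSE, stringsAsFactors = FALSE)
    fdata$modifications <- mods
    enriched <- intensity_assay(vals, fdata, scale_tag = "log2")

    gmean <- outer(baseline, rep(0, ns), "+") +
      outer(protein_fc, as.numeric(treated), "*")
    gvals <- gmean + stats::rnorm(length(gmean), 0, cfg$noise_sd)
    dimnames(gvals) <- list(proteins, design$sample_id)
    gfdata <- data.frame(parent_protein = proteins, stringsAsFactors = FALSE)
    global <- intensity_assay(gvals, gfdata, scale_tag = "log2")

    if (scenario == 2L) {
      enriched$values <- mask_missing(enriched$values, cfg)
      global$values <- mask_missing(gvals, cfg)
    }

    truth_ptms <- data.frame(
      ptm = ptm_ids, protein = proteins,
      is_differential = usage_fc != 0 | protein_fc != 0,
      confounded = protein_fc != 0,
      is_differential_usage = usage_fc != 0,
      true_log2FC_ptm = usage_fc + protein_fc,
      usage_log2FC = usage_fc, protein_log2FC = protein_fc,
      stringsAsFactors = FALSE)
    truth_peps <- data.frame(
      pepform_id = pep_ids, protein = pep_protein, ptm = pep_ptm,
      baseline = pep_base, effect = eff_pep,
      is_differential = rep(truth_ptms$is_differential, each = k),
      confounded = rep(truth_ptms$confounded, each = k),
      is_differential_usage = rep(truth_ptms$is_differential_usage, each = k),
      stringsAsFactors = FALSE)

    list(enriched = enriched, global = global, design = design,
         truth = list(ptms = truth_ptms, peptidoforms = truth_peps,
                      config = cfg, scenario = scenario))
  })
}

mask_missing <- function(m, cfg) {
  if (cfg$missing_mechanism == "mcar") {
    drop <- stats::runif(length(m)) < cfg$missing_rate
  } else {
    # logistic in intensity, calibrated so the marginal rate is approximate
    ctr <- stats::quantile(m, cfg$missing_rate, na.rm = TRUE)
    p <- stats::plogis(-(m - ctr) / 1.0)
    p <- p * cfg$missing_rate / mean(p)
    drop <- stats::runif(length(m)) < p
  }
  m[drop] <- NA_real_
  m
}

#' Simulate the full benchmark grid
#'
#' The cross of the experimental designs (conditions x replicates; 12 cells
#' by default) with the two noise settings (SD 0.2 and 0.3), giving 24
#' datasets per scenario. Each dataset records its own sub-seed and carries
#' its own exact truth table.
#'
#' @param scenario 1 or 2.
#' @param conditions,replicates,noise_sds Grid axes.
#' @param n_ptms,n_pepforms_per_ptm Per-dataset sizes.
#' @param seed Base seed; dataset i uses `seed + i`.
#' @return List of datasets as returned by [simulate_scenario()], with a
#'   `grid` attribute describing the cells.
#' @export
simulate_benchmark_grid <- function(scenario = 1L, conditions = c(2L, 3L, 4L),
                                    replicates = c(2L, 3L, 5L, 10L),
                                    noise_sds = c(0.2, 0.3),
                                    n_ptms = 1000L, n_pepforms_per_ptm = 10L,
                                    seed = 1L) {
  grid <- expand.grid(n_conditions = conditions, n_replicates = replicates,
                      noise_sd = noise_sds)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- scenario_config(
      n_ptms = n_ptms, n_pepforms_per_ptm = n_pepforms_per_ptm,
      n_conditions = grid$n_conditions[i],
      n_replicates = grid$n_replicates[i],
      noise_sd = grid$noise_sd[i],
      n_confounded = as.integer(n_ptms %/% 4L),
      seed = seed + i)
    out[[i]] <- simulate_scenario(cfg, scenario = scenario)
  }
  attr(out, "grid") <- grid
  out
}

#' True log2 fold changes of the spike-in design
#'
#' Per pairwise mixture comparison: the fold change of the spiked peptides
#' without protein adjustment, and after adjusting for the background
#' "parent" protein. The mix4-vs-mix1 comparison is the internal control for
#' usage analysis (adjusted fold change 0).
#'
#' @return Data frame with `comparison`, `unadjusted_log2FC`,
#'   `adjusted_log2FC`.
#' @export
spikein_truth <- function() {
  data.frame(
    comparison = c("mix2_vs_mix1", "mix3_vs_mix1", "mix4_vs_mix1",
                   "mix3_vs_mix2", "mix4_vs_mix2", "mix4_vs_mix3"),
    unadjusted_log2FC = c(-1, 0, -1, 1, 0, -1),
    adjusted_log2FC = c(-1, 1, 0, 2, 1, -1),
    stringsAsFactors = FALSE)
}

#' Simulate the spike-in emulation
#'
#' Fifty modified peptides are "spiked" into four background mixtures (two
#' replicates each) so that their unadjusted log2 fold changes between mixes
#' equal the design truth and the protein-adjusted (usage) fold changes equal
#' the adjusted truth — per-mix spike levels (0, -1, 0, -1) and nominal
#' parent-protein levels (0, 0, -1, -1). Mixes 3 and 4 additionally receive a
#' global loading shift affecting every enriched row, which median centering
#' must remove (analyses without normalization break down on the comparisons
#' where loading differs). By default the spiked features are generated
#' *uncorrelated* with their nominal background parent protein — the design
#' flaw of this layout: the background does not contain the true parent
#' proteins — while `correlated = TRUE` shares the protein-level biological
#' noise between the protein row and its peptides, as in a real experiment.
#'
#' @param n_spiked Number of spiked peptidoforms.
#' @param n_background_proteins Background (non-differential) proteins.
#' @param replicates_per_mix Replicates per mixture.
#' @param noise_sd Technical noise SD (log2).
#' @param bio_sd SD of the protein-level biological noise term.
#' @param loading_shift Log2 loading offset applied to all enriched rows of
#'   mixes 3 and 4.
#' @param correlated Share protein biological noise with the spiked peptides.
#' @param seed Integer seed.
#' @return List with `enriched`, `global`, `design` and `truth` (the
#'   comparison table from [spikein_truth()], the spiked feature ids, per-mix
#'   level vectors).
#' @export
simulate_spikein <- function(n_spiked = 50L, n_background_proteins = 450L,
                             replicates_per_mix = 2L, noise_sd = 0.2,
                             bio_sd = 0.2, loading_shift = 0.5,
                             correlated = FALSE, seed = 1L) {
  with_seed(seed, {
    mixes <- paste0("mix", 1:4)
    design <- data.frame(
      sample_id = paste0(rep(mixes, each = replicates_per_mix), "_r",
                         rep(seq_len(replicates_per_mix), 4L)),
      condition = rep(mixes, each = replicates_per_mix),
      stringsAsFactors = FALSE)
    ns <- nrow(design)
    mix_of <- match(design$condition, mixes)

    spike_levels <- c(0, -1, 0, -1)       # unadjusted per-mix levels
    protein_levels <- c(0, 0, -1, -1)     # background "parent" per-mix levels
    loading <- c(0, 0, loading_shift, loading_shift)

    spike_prot <- sprintf("SPIKEPROT%03d", seq_len(n_spiked))
    spike_ids <- sprintf("%s_pep", spike_prot)
    bg_prot <- sprintf("BGPROT%04d", seq_len(n_background_proteins))

    s_base <- stats::rnorm(n_spiked, 20, 1)
    b_base <- stats::rnorm(n_background_proteins, 22, 2)
    prot_bio <- matrix(stats::rnorm(n_spiked * ns, 0, bio_sd), n_spiked, ns)

    spike_vals <- outer(s_base, spike_levels[mix_of] + loading[mix_of], "+") +
      (if (correlated) prot_bio else 0) +
      stats::rnorm(n_spiked * ns, 0, noise_sd)
    bg_vals <- outer(b_base, loading[mix_of], "+") +
      stats::rnorm(n_background_proteins * ns, 0, noise_sd)
    evals <- rbind(spike_vals, bg_vals)
    dimnames(evals) <- list(c(spike_ids, paste0(bg_prot, "_pep")),
                            design$sample_id)

    mk_mods <- function(n, mod, site) lapply(seq_len(n), function(i)
      data.frame(mod_name = mod, residue = "K", peptide_site = 1L,
                 protein_site = site, stringsAsFactors = FALSE))
    efdata <- data.frame(
      sequence = c(sprintf("KSPIKEPEP%03d", seq_len(n_spiked)),
                   sprintf("KBGPEP%04d", seq_len(n_background_proteins))),
      parent_protein = c(spike_prot, bg_prot),
      peptide_start = 10L, is_decoy = FALSE, is_contaminant = FALSE,
      stringsAsFactors = FALSE)
    efdata$modifications <- mk_mods(nrow(efdata), "GlyGly (K)", 10L)
    enriched <- intensity_assay(evals, efdata, scale_tag = "log2")

    g_spike <- outer(stats::rnorm(n_spiked, 21, 1),
                     protein_levels[mix_of] + loading[mix_of], "+") +
      prot_bio + stats::rnorm(n_spiked * ns, 0, noise_sd)
    g_bg <- outer(stats::rnorm(n_background_proteins, 22, 2),
                  loading[mix_of], "+") +
      stats::rnorm(n_background_proteins * ns, 0, noise_sd)
    gvals <- rbind(g_spike, g_bg)
    dimnames(gvals) <- list(c(spike_prot, bg_prot), design$sample_id)
    gfdata <- data.frame(parent_protein = c(spike_prot, bg_prot),
                         stringsAsFactors = FALSE)
    global <- intensity_assay(gvals, gfdata, scale_tag = "log2")

    ptm_ids <- sprintf("%s (GlyGly (K)) %d", spike_prot, 10L)
    list(enriched = enriched, global = global, design = design,
         truth = list(comparisons = spikein_truth(),
                      spiked_pepforms = spike_ids,
                      spiked_ptms = ptm_ids,
                      spike_levels = stats::setNames(spike_levels, mixes),
                      protein_levels = stats::setNames(protein_levels, mixes),
                      loading = stats::setNames(loading, mixes),
                      seed = seed))
  })
}

#' Randomly relabel single-condition samples into two pseudo-groups
#'
#' Splits the samples exactly in half into `"mock"` and `"control"` labels.
#' Every feature later called significant between the two pseudo-groups is a
#' false positive, so the resulting p-values should be uniform when type I
#' error is controlled. An odd sample count is split floor/ceiling with a
#' warning.
#'
#' @param sample_ids Character vector of samples from one condition (>= 4).
#' @param seed Integer seed; different seeds give different splits.
#' @return Data frame with `sample_id` and `mock_condition`.
#' @export
mock_relabel <- function(sample_ids, seed = 1L) {
  n <- length(sample_ids)
  stopifnot(n >= 4L)
  if (n %% 2L == 1L)
    warning("odd sample count; splitting ", n %/% 2L, " + ", n - n %/% 2L)
  with_seed(seed, {
    mock <- sample(sample_ids, n %/% 2L)
    data.frame(sample_id = sample_ids,
               mock_condition = ifelse(sample_ids %in% mock, "mock",
                                       "control"),
               stringsAsFactors = FALSE)
  })
}
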