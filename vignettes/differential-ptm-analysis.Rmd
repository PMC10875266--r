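---
title: "Differential abundance and usage analysis of peptidoforms and PTMs"
author: "ptmdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential abundance and usage analysis of peptidoforms and PTMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmdiff)
```

## The problem

Enrichment-based mass-spectrometry experiments quantify *peptidoforms* — a
peptide sequence together with its exact set of modifications — and the
biological questions usually live one level up, at the *PTM site*: does
phosphorylation of protein P at residue 280 change between conditions?
Two distinct questions hide behind "change":

* **Differential abundance (DPA)** — does the (site-level) intensity change,
  full stop?
* **Differential usage (DPU)** — does the intensity change *relative to the
  parent protein*? A protein that doubles takes all of its modified
  peptidoforms with it; a DPA analysis flags those sites even though the
  modification stoichiometry is untouched. DPU subtracts the summarized
  parent-protein profile so that only changes beyond the protein remain.

`ptmdiff` implements both workflows at the peptidoform and the PTM level,
together with the simulation machinery needed to verify their operating
characteristics (FDR control, sensitivity, null calibration) without any
external data.

## Data model

All data live in a `ptm_experiment`: a named collection of
features-by-samples intensity assays, feature links between levels, and one
sample-annotation table. Workflow stages never overwrite an assay — each
stage appends a new, linked assay, so the raw input is always recoverable
and any derived value can be traced to its origin. Missing intensities are
represented as absent measurements (`NA`), never as zero; a raw intensity of
0 is coerced to missing on ingest because its log is undefined and
enrichment data are dominated by genuine missingness. Peptidoform identity
is the modified sequence string itself; a duplicated identity in a report is
an error rather than a silent merge.

## The model

After filtering (a peptidoform must be observed in at least 2 samples;
decoys and contaminants removed), log2 transformation and per-sample
median (or mean) centering, the DPU workflow normalizes each peptidoform by
its parent protein:

$$y^*_{i,p,P} = y_{i,p,P} - \mu_{i,P}$$

where $\mu_{i,P}$ is the summarized intensity of protein $P$ in sample $i$.
Summaries — protein level for the normalization, PTM-site level for the
final tests — come from one robust engine: the additive two-way model

$$y_{fs} = \text{sample}_s + \text{feature}_f + \varepsilon_{fs}$$

fitted by iteratively reweighted least squares with Huber weights
(tuning constant $k = 1.345$, i.e. 95% Gaussian efficiency), feature effects
constrained to sum to zero so the sample effect is directly the consensus
profile. Missing cells are simply omitted rows of the design; a sample with
no observation among the contributing features gets a missing summary. The
residual scale is re-estimated each iteration as MAD/0.6745; convergence is
declared when the largest coefficient change drops below 1e-6 (at most 100
iterations, after which the last iterate is returned and flagged).
$k = \infty$ recovers the two-way least-squares fit exactly, which is one of
the oracle identities in the test suite.

When summarizing peptidoforms to PTM sites, a peptidoform carrying several
modifications contributes to *every* site it carries; unmodified
peptidoforms contribute to none. A PTM site is identified by the
(protein, modification, site) triple, e.g. `P10451 (Phospho (STY)) 280`;
when the peptide's start position in the protein is unknown the key falls
back to a `pep:`-prefixed peptide-relative site so that keys from different
peptides can never collide silently.

Each summarized feature is then modeled separately,

$$y_{cs} = \beta_0 + \beta_c\,\text{condition} + \varepsilon_{cs},\qquad
\varepsilon_{cs}\sim N(0,\sigma^2),$$

with arbitrary fixed-effect formulas, optional Huber M-estimation, optional
ridge shrinkage of the non-intercept coefficients (penalty chosen by
generalized cross-validation on a log-spaced grid), and optionally a single
random intercept (e.g. biological repeat) estimated by profiled REML — a
one-dimensional optimization over the log variance ratio, with fixed
effects by generalized least squares at the optimum. Residual variances are
moderated across features by empirical-Bayes squeezing toward a scaled-F
prior, contrasts $L'\beta$ are tested with moderated t-statistics on
$df_{\text{residual}} + df_{\text{prior}}$ degrees of freedom, and p-values
are Benjamini–Hochberg adjusted per contrast.

### The single-model policy

A deliberate design choice: a feature is either fitted with the *full*
requested model or reported as `no_fit` — never silently downgraded to a
simpler model when data are missing. Adaptive downgrading (dropping a
random-effect term as soon as a data point is missing) treats, say,
biological repeat 1 of the control group and biological repeat 1 of the
treatment group as the same unit, ignores a known variance component, and
underestimates standard errors. `no_fit` features are reported with missing
statistics, excluded from the BH denominator, and appended last in
performance curves, which makes "cannot fit" visible rather than silently
optimistic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_samples` | 2 | minimum observed samples per peptidoform |
| `center` | median | per-sample centering statistic (log2 scale) |
| `huber_k` | 1.345 | Huber tuning constant (95% Gaussian efficiency) |
| `tol`, `max_iter` | 1e-6, 100 | IRLS convergence controls |
| `protein_source` | global | protein summaries from the non-enriched run when present, else from the enriched data itself |
| `shared_policy` | exclude | shared peptides (several parent accessions) are excluded from protein summaries and PTM analysis; `first` assigns them to the first accession |
| `moderation` | TRUE | empirical-Bayes variance squeezing |
| `alpha` | 0.05 | BH significance level |

Shared-peptide exclusion avoids double counting when a peptide cannot be
attributed to one protein; the alternative (`first`) is exposed because
some search engines already order accessions by evidence.

## What the simulators emulate — and what they do not

`simulate_scenario()` generates the two-level benchmark: per parent protein
(one PTM per protein) a baseline log2 intensity `Normal(25, 2)`; per
peptidoform (10 per PTM) a fixed offset `Normal(0, 1)`; i.i.d. Gaussian
noise with SD 0.2 (low-variance setting) or 0.3. Of 1000 PTMs, 500 are
differentially abundant with balanced ±1 log2 effects: 250 carry a *pure
usage* effect (only the modified peptidoforms move) and 250 are *confounded*
(the parent protein moves, dragging its peptidoforms and its
global-profiling row along, with no usage change). This makes
differential-abundance truth and differential-usage truth distinct columns
of the truth table: a correct DPU analysis must find the 250 pure-usage
PTMs and must *not* find the 250 confounded ones. Scenario 2 masks entries
of both assays completely at random at rate 0.2 (an intensity-dependent
MNAR option is provided since real missingness is partly abundance-driven).
The baseline/offset/effect magnitudes and the missingness rate are this
package's own calibration choices, exposed as configuration.

`simulate_spikein()` emulates a four-mixture spike-in with 50 modified
peptides at known per-mix levels (0, −1, 0, −1), nominal background parent
proteins at (0, 0, −1, −1) — so the six pairwise comparisons have known
unadjusted and adjusted log2 fold changes (`spikein_truth()`), with
mix4-vs-mix1 as the internal control for usage analysis — and a global
loading shift (+0.5 log2) on every enriched row of mixes 3 and 4. Median
centering must absorb that shift; an unnormalized analysis breaks down on
exactly the comparisons where loading differs, which the test suite
demonstrates. By default the spiked features are generated *uncorrelated*
with their nominal parent proteins, reproducing the structural flaw of such
designs (the background does not contain the true parents); a correlated
variant shares the protein-level biological noise (SD 0.2) between protein
and peptides as in a real experiment.

Neither generator attempts chromatographic artifacts, interference,
intensity-dependent variance, or shared peptides; passing the benchmark
therefore demonstrates correct statistical behaviour under the stated
generative model, not robustness to every failure mode of real data.

`mock_relabel()` supports null calibration on real or simulated data:
samples from a single condition are split exactly in half into "mock" and
"control"; every discovery is then a false positive and the p-value
distribution should be uniform, which `pvalue_uniformity()` checks with a
one-sample Kolmogorov–Smirnov test.

## Numerical choices and degenerate inputs

* Ranking for tpr–fdp and ROC curves breaks ties deterministically:
  p-value, then |t| descending, then feature id.
* A single-feature summary is the feature's own row (feature effect 0);
  a single tested feature gets `adj_pval = pval`.
* Centering a sample whose values are all missing is an error; a sample
  unobserved within one summarization group merely gets a missing summary.
* Mixed-model residual df use `n - rank(X) - 1` (one df for the variance
  component), not Satterthwaite; moderated robust fits keep unadjusted df.
  Both are documented approximations.
* `df_prior = Inf` (all variances shrunk to the prior) yields a normal
  reference distribution.
* The spike-in emulation and all generators restore the global RNG state,
  and every dataset records its sub-seed.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_scenario(scenario_config(n_replicates = 10, seed = 1))
x <- build_experiment(sim$design, sim$enriched, sim$global)
run <- run_dpu(x, workflow_config(mode = "dpu", level = "ptm"))
confusion_at_alpha(run$results, sim$truth$ptms, alpha = 0.05)
```

On this dataset the workflow calls ~260 PTMs at the 5% BH level with an
observed false discovery proportion around 4% and full sensitivity for the
pure-usage effects (exact numbers depend on the seed; the test suite and
`scripts/acceptance.R` recompute them).

## Problem sizes used in the checks

The packaged checks run the full benchmark conditions where the claim
depends on them (1000 PTMs × 10 peptidoforms, 2 × 10 samples, 10 seeds for
the FDR check) and scaled-down grids (e.g. 10 PTMs × 2 peptidoforms per
dataset) where only structure or plumbing is under test; each test states
its own sizes. Mock calibration uses 400 PTMs over 10 single-condition
samples, five relabelings, at both analysis levels.

## Known limitations

* One random intercept only; no crossed or nested random designs.
* No imputation — by design; all statistics use observed entries only.
* Protein summaries from the enriched assay itself are biased toward the
  modified peptidoforms when a site dominates its protein's peptidoform
  set; the non-enriched source is preferred whenever available.
* BH is applied per contrast within an analysis level; moderation pools
  within a level, never across peptidoform and PTM levels jointly.
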