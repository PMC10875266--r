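# Shared fixtures and independent oracles used across the test files.

tiny_design <- function(n_per = 3L, conds = c("A", "B")) {
  data.frame(
    sample_id = paste0(rep(conds, each = n_per), seq_len(n_per)),
    condition = rep(conds, each = n_per),
    stringsAsFactors = FALSE)
}

tiny_assay <- function(values, scale_tag = "log2", fdata = NULL) {
  intensity_assay(values, fdata, scale_tag = scale_tag)
}

rand_matrix <- function(nf, ns, seed, missing = 0, cols = NULL) {
  set.seed(seed)
  if (is.null(cols)) cols <- sprintf("s%02d", seq_len(ns))
  m <- matrix(rnorm(nf * ns, 20, 2), nf, ns,
              dimnames = list(sprintf("f%02d", seq_len(nf)), cols))
  if (missing > 0) m[runif(length(m)) < missing] <- NA
  m
}

# Independent IRLS oracle for the two-way robust summary: MASS::rlm on the
# long-format data with sum-coded feature effects.
rlm_summary_oracle <- function(x, k = 1.345) {
  obs <- which(!is.na(x), arr.ind = TRUE)
  df <- data.frame(y = x[obs],
                   s = factor(obs[, 2], levels = seq_len(ncol(x))),
                   f = factor(obs[, 1]))
  fit <- MASS::rlm(y ~ 0 + s + f, data = df,
                   contrasts = list(f = "contr.sum"),
                   k = k, maxit = 200, acc = 1e-10)
  out <- rep(NA_real_, ncol(x))
  cf <- coef(fit)[paste0("s", seq_len(ncol(x)))]
  out[!is.na(cf)] <- cf[!is.na(cf)]
  names(out) <- colnames(x)
  out
}

# Closed-form two-way least-squares sample effects for complete matrices:
# with feature effects summing to zero, the sample effect is the column mean.
ls_summary_oracle <- function(x) colMeans(x)

# Brute-force Benjamini-Hochberg step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Independent moment-matching of the scaled-F variance prior on the
# log-variance scale (numeric root finding).
squeeze_oracle <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  target <- mean((e - ebar)^2) * length(e) / (length(e) - 1) -
    mean(trigamma(df / 2))
  if (target > 0) {
    g <- function(d0) trigamma(d0 / 2) - target
    d0 <- uniroot(g, c(1e-6, 1e8))$root
    s2_prior <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s2_prior <- exp(ebar)
  }
  post <- if (is.infinite(d0)) rep(s2_prior, length(s2)) else
    (d0 * s2_prior + df * s2) / (d0 + df)
  list(s2_prior = s2_prior, df_prior = d0, s2_post = post)
}

# Dense grid-search REML oracle for the single-random-intercept model,
# coded directly from the profiled criterion with plain matrix inverses.
reml_grid_oracle <- function(y, X, g, grid = seq(-12, 8, by = 0.005)) {
  Z <- model.matrix(~ 0 + g)
  n <- length(y); p <- ncol(X)
  crit <- vapply(grid, function(lg) {
    V <- diag(n) + exp(lg) * tcrossprod(Z)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    q <- drop(t(r) %*% Vi %*% r)
    as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
                 (n - p) * log(q))
  }, numeric(1))
  lg <- grid[which.min(crit)]
  V <- diag(n) + exp(lg) * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- drop(solve(XtViX, t(X) %*% Vi %*% y))
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  list(loggamma = lg, beta = beta, sigma = sqrt(sigma2))
}

# Direct 2x2 counting oracle for confusion metrics and ranked curves.
counting_confusion_oracle <- function(called, pos) {
  tp <- sum(called & pos); fp <- sum(called & !pos)
  fn <- sum(!called & pos); tn <- sum(!called & !pos)
  list(fpr = fp / (fp + tn), sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       accuracy = (tp + tn) / length(pos), fdp = fp / max(1, fp + tp),
       n_called = tp + fp)
}

# Random modified peptide sequence for parser round-trip property tests.
random_modified_sequence <- function(seed) {
  set.seed(seed)
  len <- sample(5:15, 1)
  aa <- sample(LETTERS[-c(2, 10, 15, 21, 24, 26)], len, replace = TRUE)
  n_mods <- sample(0:3, 1)
  sites <- sort(sample(0:len, n_mods))
  mods <- data.frame(
    mod_name = sample(c("Phospho (STY)", "Oxidation (M)", "GlyGly (K)"),
                      max(n_mods, 1), replace = TRUE)[seq_len(n_mods)],
    residue = ifelse(sites == 0, "", aa[pmax(sites, 1)]),
    peptide_site = sites, stringsAsFactors = FALSE)
  list(stripped = paste(aa, collapse = ""), mods = mods,
       text = reconstruct_sequence(paste(aa, collapse = ""), mods))
}

# Minimal two-level dataset for workflow tests.
small_sim <- function(seed = 5, n_ptms = 40, n_replicates = 4, ...) {
  simulate_scenario(scenario_config(n_ptms = n_ptms,
                                    n_replicates = n_replicates,
                                    seed = seed, ...))
}
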