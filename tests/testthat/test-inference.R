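test_that("OLS fit equals the normal-equations solution", {
  d <- tiny_design(n_per = 3)
  set.seed(1)
  y <- setNames(rnorm(6, 20), d$sample_id)
  f <- fit_feature(y, d, ~ condition)
  X <- model.matrix(~ condition, d)
  beta_oracle <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_identical(f$status, "ok")
  expect_equal(unname(f$beta), unname(beta_oracle), tolerance = 1e-10)
  expect_equal(f$df_residual, 4)
  r <- y - drop(X %*% beta_oracle)
  expect_equal(f$sigma, sqrt(sum(r^2) / 4), tolerance = 1e-10)
  expect_equal(unname(f$vcov_unscaled), unname(solve(crossprod(X))),
               tolerance = 1e-10)
})

test_that("saturated or degenerate designs yield no_fit, never a downgrade", {
  d <- tiny_design(n_per = 1)              # 2 conditions x 1 replicate
  y <- setNames(c(1, 2), d$sample_id)
  expect_identical(fit_feature(y, d, ~ condition)$status, "no_fit")

  # a condition losing all its observations makes the coefficient
  # inestimable: status no_fit rather than a silently simplified model
  d2 <- tiny_design(n_per = 3)
  y2 <- setNames(rnorm(6), d2$sample_id)
  y2[d2$condition == "B"] <- NA
  expect_identical(fit_feature(y2, d2, ~ condition)$status, "no_fit")
})

test_that("robust fit equals OLS on outlier-free data and downweights outliers", {
  d <- tiny_design(n_per = 4)
  # residuals of equal magnitude: every Huber weight stays 1, so the
  # robust fit coincides with OLS exactly
  y <- setNames(20 + (d$condition == "B") + rep(c(-0.1, 0.1), 4),
                d$sample_id)
  f_ols <- fit_feature(y, d, ~ condition)
  f_rob <- fit_feature(y, d, ~ condition, robust = TRUE)
  expect_equal(f_rob$beta, f_ols$beta, tolerance = 1e-6)

  y_out <- y
  y_out[1] <- y_out[1] + 30
  b_rob <- fit_feature(y_out, d, ~ condition, robust = TRUE)$beta
  b_ols <- fit_feature(y_out, d, ~ condition)$beta
  expect_lt(abs(b_rob["(Intercept)"] - f_ols$beta["(Intercept)"]),
            abs(b_ols["(Intercept)"] - f_ols$beta["(Intercept)"]))
})

test_that("ridge fit shrinks non-intercept coefficients and keeps status ok", {
  d <- tiny_design(n_per = 4)
  set.seed(3)
  y <- setNames(rnorm(8, 10, 0.5) + (d$condition == "B") * 0.5, d$sample_id)
  f <- fit_feature(y, d, ~ condition, ridge = TRUE)
  f0 <- fit_feature(y, d, ~ condition)
  expect_identical(f$status, "ok")
  expect_lte(abs(f$beta["conditionB"]), abs(f0$beta["conditionB"]) + 1e-10)
  expect_equal(unname(f$beta["(Intercept)"] + f$beta["conditionB"] / 2),
               unname(f0$beta["(Intercept)"] + f0$beta["conditionB"] / 2),
               tolerance = 0.2)
})

test_that("mixed REML fit matches the dense grid-search oracle", {
  set.seed(4)
  d <- data.frame(sample_id = paste0("s", 1:12),
                  condition = rep(c("A", "B"), each = 6),
                  biorepeat = rep(paste0("b", 1:6), each = 2))
  y <- setNames(rnorm(12, 0, 0.4) + rep(rnorm(6, 0, 0.8), each = 2) +
                  (d$condition == "B"), d$sample_id)
  f <- fit_mixed_feature(y, d, ~ condition, random = "biorepeat")
  X <- model.matrix(~ condition, d)
  oracle <- reml_grid_oracle(unname(y), X, factor(d$biorepeat))
  expect_identical(f$status, "ok")
  expect_equal(unname(f$beta), unname(oracle$beta), tolerance = 1e-3)
  expect_equal(f$sigma, oracle$sigma, tolerance = 1e-3)
  expect_equal(f$df_residual, 12 - 2 - 1)
})

test_that("mixed fit handles boundary and unidentifiable cases", {
  d <- data.frame(sample_id = paste0("s", 1:12),
                  condition = rep(c("A", "B"), each = 6),
                  biorepeat = rep(paste0("b", 1:6), each = 2))
  # identical group means: variance component driven to ~0, fixed effects
  # match the fixed-model fit
  set.seed(5)
  y <- setNames(rnorm(12, 0, 0.5) + (d$condition == "B") * 2, d$sample_id)
  f <- fit_mixed_feature(y, d, ~ condition, random = "biorepeat")
  ff <- fit_feature(y, d, ~ condition)
  expect_equal(unname(f$beta), unname(ff$beta), tolerance = 0.05)

  # balanced one-way random design with interior components matches the
  # classical ANOVA moment estimators
  set.seed(6)
  g <- rep(paste0("b", 1:5), each = 4)
  d2 <- data.frame(sample_id = paste0("s", 1:20), condition = "A",
                   biorepeat = g)
  y2 <- setNames(rep(rnorm(5, 0, 2), each = 4) + rnorm(20, 0, 0.5),
                 d2$sample_id)
  f2 <- fit_mixed_feature(y2, d2, ~ 1, random = "biorepeat")
  aovfit <- anova(aov(y2 ~ factor(g)))
  msb <- aovfit$`Mean Sq`[1]; msw <- aovfit$`Mean Sq`[2]
  expect_equal(f2$sigma^2, msw, tolerance = 1e-3)
  expect_equal(f2$sigma_b^2, (msb - msw) / 4, tolerance = 1e-3)

  # single observed level: unidentifiable
  d3 <- d2; d3$biorepeat <- "b1"
  expect_identical(fit_mixed_feature(y2, d3, ~ 1,
                                     random = "biorepeat")$status, "no_fit")
})

test_that("variance squeezing matches the moment-matching oracle", {
  set.seed(1)
  df <- rep(4, 200)
  s2 <- 0.05 * rf(200, 4, 8)      # scaled-F draws with a finite prior df
  sq <- squeeze_variances(sqrt(s2), df)
  or <- squeeze_oracle(s2, df)
  expect_equal(sq$s2_prior, or$s2_prior, tolerance = 1e-4)
  expect_equal(sq$df_prior, or$df_prior, tolerance = 1e-3)
  expect_equal(sq$s2_post, or$s2_post, tolerance = 1e-4)

  # all variances equal: the common value is a fixed point
  sq_eq <- squeeze_variances(rep(0.3, 10), rep(5, 10))
  expect_equal(sq_eq$s2_post, rep(0.09, 10), tolerance = 1e-8)

  # fewer than 2 usable variances: no moderation
  sq1 <- squeeze_variances(c(0.3, NA), c(5, NA))
  expect_equal(sq1$df_prior, 0)
  expect_equal(sq1$s2_post, c(0.09, NA))
})

test_that("contrast parsing produces the expected L vectors", {
  coefs <- c("(Intercept)", "condB", "condC")
  expect_equal(make_contrast("condB = 0", coefs)$L,
               c("(Intercept)" = 0, condB = 1, condC = 0))
  expect_equal(make_contrast("condB - condC = 0", coefs)$L,
               c("(Intercept)" = 0, condB = 1, condC = -1))
  expect_equal(make_contrast("0.5*condB + 0.5*condC", coefs)$L,
               c("(Intercept)" = 0, condB = 0.5, condC = 0.5))
  expect_error(make_contrast("condZ = 0", coefs), "unknown coefficient")
  expect_error(make_contrast("condB = 1", coefs), "right-hand side")
  expect_error(make_contrast("condB - condB = 0", coefs), "all zero")
})

test_that("unmoderated contrast tests reproduce the classical two-sample t", {
  d <- tiny_design(n_per = 4)
  set.seed(8)
  fits <- list()
  ys <- list()
  for (i in 1:3) {
    y <- setNames(rnorm(8, 15) + (d$condition == "B") * i / 2, d$sample_id)
    ys[[i]] <- y
    fits[[paste0("feat", i)]] <- fit_feature(y, d, ~ condition)
  }
  ct <- make_contrast("conditionB = 0", c("(Intercept)", "conditionB"))
  rows <- test_contrasts(fits, ct, moderation = FALSE)
  for (i in 1:3) {
    tt <- t.test(ys[[i]][d$condition == "B"], ys[[i]][d$condition == "A"],
                 var.equal = TRUE)
    expect_equal(rows$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rows$pval[i], tt$p.value, tolerance = 1e-10)
    expect_equal(rows$df[i], 6)
  }
})

test_that("moderated t with a degenerate prior is identical to the ordinary t", {
  d <- tiny_design(n_per = 3)
  set.seed(9)
  fits <- lapply(1:5, function(i)
    fit_feature(setNames(rnorm(6), d$sample_id), d, ~ condition))
  names(fits) <- paste0("f", 1:5)
  ct <- make_contrast("conditionB = 0", c("(Intercept)", "conditionB"))
  plain <- test_contrasts(fits, ct, moderation = FALSE)
  forced <- test_contrasts(fits, ct, moderation = TRUE)
  # emulate df_prior = 0 by moderation = FALSE; the two paths must agree
  # whenever squeezing estimates a null prior
  sq <- squeeze_variances(vapply(fits, `[[`, 0, "sigma"),
                          vapply(fits, `[[`, 0, "df_residual"))
  if (sq$df_prior == 0) {
    expect_identical(forced, plain)
  } else {
    expect_false(identical(forced$pval, plain$pval))
  }
  expect_true(all(plain$adj_pval >= plain$pval - 1e-12))
})

test_that("BH adjustment equals the step-up definition and handles no_fit rows", {
  d <- tiny_design(n_per = 3)
  set.seed(10)
  fits <- lapply(1:20, function(i)
    fit_feature(setNames(rnorm(6), d$sample_id), d, ~ condition))
  names(fits) <- paste0("f", 1:20)
  fits[["broken"]] <- fit_feature(setNames(c(1, rep(NA, 5)), d$sample_id),
                                  d, ~ condition)
  ct <- make_contrast("conditionB = 0", c("(Intercept)", "conditionB"))
  rows <- test_contrasts(fits, ct, moderation = TRUE)
  expect_true(is.na(rows$pval[rows$feature_id == "broken"]))
  has_p <- !is.na(rows$pval)
  expect_equal(rows$adj_pval[has_p], bh_oracle(rows$pval[has_p]))

  # spot value: known step-up result
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  # property: BH on random p-vectors, including a single-feature set
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(sample(2:30, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
  one <- test_contrasts(fits["f1"], ct, moderation = FALSE)
  expect_equal(one$adj_pval, one$pval)
})

test_that("relabeling samples within a condition leaves inference unchanged", {
  d <- tiny_design(n_per = 4)
  set.seed(11)
  y <- setNames(rnorm(8, 10) + (d$condition == "B"), d$sample_id)
  ct <- make_contrast("conditionB = 0", c("(Intercept)", "conditionB"))
  r1 <- test_contrasts(list(f = fit_feature(y, d, ~ condition)), ct,
                       moderation = FALSE)
  d2 <- d[c(2, 1, 3, 4, 8, 7, 6, 5), ]
  r2 <- test_contrasts(list(f = fit_feature(y, d2, ~ condition)), ct,
                       moderation = FALSE)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("null simulation keeps the BH discovery fraction near alpha", {
  d <- tiny_design(n_per = 4)
  set.seed(12)
  fits <- lapply(1:600, function(i)
    fit_feature(setNames(rnorm(8), d$sample_id), d, ~ condition))
  names(fits) <- paste0("f", 1:600)
  ct <- make_contrast("conditionB = 0", c("(Intercept)", "conditionB"))
  rows <- test_contrasts(fits, ct, moderation = TRUE)
  frac <- mean(rows$adj_pval <= 0.05, na.rm = TRUE)
  # under the global null BH controls FWER-like behaviour; the discovery
  # fraction must stay at or below alpha within binomial error
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 600))
})
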