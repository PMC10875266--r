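test_that("robust summary handles degenerate and clean two-way cases", {
  one <- matrix(c(5, 7, 9), 1, 3, dimnames = list("f1", paste0("s", 1:3)))
  expect_equal(unname(robust_summary(one)[1:3]), c(5, 7, 9),
               ignore_attr = TRUE)

  # two complete features offset by a constant, no outliers: all Huber
  # weights stay 1 and the sample effects are the per-sample means
  x <- rbind(f1 = c(10, 11, 12, 13), f2 = c(12, 13, 14, 15))
  colnames(x) <- paste0("s", 1:4)
  expect_equal(unname(robust_summary(x)[1:4]), ls_summary_oracle(x),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("an outlying cell pulls the summary between mean and median and matches the IRLS oracle", {
  set.seed(10)
  x <- matrix(rnorm(15, 20, 0.5), 3, 5,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:5)))
  x[2, 3] <- x[2, 3] + 50
  got <- robust_summary(x)
  expect_true(got["s3"] > median(x[, 3]) && got["s3"] < mean(x[, 3]))
  expect_equal(unname(got[1:5]), unname(rlm_summary_oracle(x)),
               tolerance = 1e-6)
})

test_that("robust summary equals the IRLS oracle on random small matrices", {
  for (seed in 1:12) {
    nf <- sample(2:5, 1)
    ns <- sample(2:5, 1)
    x <- rand_matrix(nf, ns, seed = 100 + seed,
                     missing = if (seed %% 3 == 0) 0.15 else 0)
    # oracle needs every sample observed and a connected design
    if (any(colSums(!is.na(x)) == 0) || any(rowSums(!is.na(x)) == 0)) next
    got <- robust_summary(x)
    want <- rlm_summary_oracle(x)
    expect_equal(unname(got[seq_len(ns)]), unname(want), tolerance = 1e-6)
  }
})

test_that("huber_k = Inf reduces to least squares; shift equivariance holds", {
  for (seed in 1:5) {
    x <- rand_matrix(4, 4, seed = 200 + seed)
    expect_equal(unname(robust_summary(x, huber_k = Inf)[1:4]),
                 unname(ls_summary_oracle(x)), tolerance = 1e-8)
    shifted <- x
    shifted[, 2] <- shifted[, 2] + 3.7
    expect_equal(unname(robust_summary(shifted)[2]),
                 unname(robust_summary(x)[2]) + 3.7, tolerance = 1e-6)
  }
  # unobserved sample columns give missing summaries
  x <- rand_matrix(3, 3, seed = 300)
  x[, 2] <- NA
  s <- robust_summary(x)
  expect_true(is.na(s["s02"]) && !anyNA(s[c("s01", "s03")]))
})

test_that("protein summarization is per-block and compositional", {
  m <- rand_matrix(6, 4, seed = 301)
  fd <- data.frame(parent_protein = c("P1", "P1", "P1", "P2", "P2", "P3"))
  a <- tiny_assay(m, fdata = fd)
  ps <- summarize_proteins(a)
  expect_setequal(feature_ids(ps), c("P1", "P2", "P3"))
  expect_equal(ps$fdata$n_children[match(c("P1", "P2", "P3"),
                                         ps$fdata$parent_protein)],
               c(3L, 2L, 1L))

  # single-peptidoform protein passes through unchanged
  expect_equal(ps$values["P3", ], m[6, ])
  # compositional: equals robust_summary on the submatrix
  expect_equal(unname(ps$values["P1", ]),
               unname(robust_summary(m[1:3, ])[1:4]))
  # block independence: permuting P2's rows leaves P1's summary unchanged
  m2 <- m[c(1:3, 5, 4, 6), ]
  rownames(m2) <- rownames(m)
  a2 <- tiny_assay(m2, fdata = fd)
  expect_equal(summarize_proteins(a2)$values["P1", ], ps$values["P1", ])

  # shared peptides excluded by default, assigned under "first"
  fd_shared <- data.frame(parent_protein = c("P1;P2", "P1", "P1", "P2",
                                             "P2", "P3"))
  ashr <- tiny_assay(m, fdata = fd_shared)
  expect_warning(ex <- summarize_proteins(ashr), "skipped")
  expect_equal(ex$fdata$n_children[ex$fdata$parent_protein == "P1"], 2L)
  fir <- summarize_proteins(ashr, shared_policy = "first")
  expect_equal(fir$fdata$n_children[fir$fdata$parent_protein == "P1"], 3L)
})

test_that("usage normalization subtracts the protein profile entrywise", {
  m <- matrix(c(20.5, 21, NA, 19), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  fd <- data.frame(parent_protein = c("PA", "PB"))
  a <- tiny_assay(m, fdata = fd)
  mu <- matrix(c(18, 20, 17.5, NA), 2, 2,
               dimnames = list(c("PA", "PB"), c("s1", "s2")))
  ps <- tiny_assay(mu, fdata = data.frame(parent_protein = c("PA", "PB")))
  u <- usage_normalize(a, ps)
  expect_equal(u$values["p1", "s1"], 20.5 - 18)
  expect_true(is.na(u$values["p1", "s2"]))        # y missing -> missing
  expect_true(is.na(u$values["p2", "s2"]))        # mu missing -> missing
  expect_identical(u$scale_tag, "log2-usage")

  # protein absent from the summaries: feature excluded and reported
  fd2 <- data.frame(parent_protein = c("PA", "GHOST"))
  a2 <- tiny_assay(m, fdata = fd2)
  u2 <- usage_normalize(a2, ps)
  expect_identical(feature_ids(u2), "p1")
  expect_identical(attr(u2, "dropped"), "p2")
})

test_that("self-normalization closure: re-summarizing usages gives zero", {
  m <- rand_matrix(9, 5, seed = 400)
  fd <- data.frame(parent_protein = rep(c("P1", "P2", "P3"), each = 3))
  a <- tiny_assay(m, fdata = fd)
  ps <- summarize_proteins(a)
  u <- usage_normalize(a, ps)
  re <- summarize_proteins(u)
  expect_lt(max(abs(re$values)), 1e-6)
})

test_that("peptidoforms expand to one group per carried PTM", {
  m <- rand_matrix(3, 2, seed = 500)
  rownames(m) <- c("pepA", "pepB", "pepC")
  mods <- list(
    data.frame(mod_name = c("Phospho (STY)", "Oxidation (M)"),
               residue = c("S", "M"), peptide_site = c(2L, 5L)),
    data.frame(mod_name = character(0), residue = character(0),
               peptide_site = integer(0)),
    data.frame(mod_name = "Phospho (STY)", residue = "S",
               peptide_site = 4L))
  fd <- data.frame(sequence = c("ASDFMK", "PEPK", "AAASK"),
                   parent_protein = "P1",
                   peptide_start = c(10L, 1L, 8L))
  fd$modifications <- mods
  a <- tiny_assay(m, fdata = fd)
  link <- expand_to_ptm(a, "pep", "ptm")
  # pepA carries two PTMs, pepB none; pepA site 2 from start 10 and
  # pepC site 4 from start 8 both land on protein site 11
  expect_equal(sum(link$map$child_id == "pepA"), 2L)
  expect_false("pepB" %in% link$map$child_id)
  shared_key <- "P1 (Phospho (STY)) 11"
  expect_equal(sum(link$map$parent_id == shared_key), 2L)

  sa <- summarize_ptms(a, link)
  expect_equal(sa$fdata$n_children[sa$fdata$ptm == shared_key], 2L)
  # compositional check against a direct robust_summary call
  expect_equal(unname(sa$values[shared_key, ]),
               unname(robust_summary(m[c("pepA", "pepC"), ])[1:2]))
  # single-peptidoform PTM reproduces the peptidoform row exactly
  oxi_key <- "P1 (Oxidation (M)) 14"
  expect_equal(sa$values[oxi_key, ], m["pepA", ])
  # two parallel peptidoforms: summary resides in the middle
  mid <- sa$values[shared_key, ]
  expect_true(all(mid >= pmin(m["pepA", ], m["pepC", ]) - 1e-9 &
                    mid <= pmax(m["pepA", ], m["pepC", ]) + 1e-9))
})
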