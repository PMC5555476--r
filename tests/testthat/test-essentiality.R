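test_that("Bayes Factors approach the closed-form normal log-ratio on large training sets", {
  ## essentials ~ N(-3,1), nonessentials ~ N(0,1); a 4-guide gene with all
  ## fc = -3 has BF -> 4 * log2(N(-3;-3,1)/N(-3;0,1)) = 4 * 4.5/ln(2)
  tr <- normal_training_fc(n_ref = 25L, guides_per_ref = 400L, mu_ess = -3,
                           extra = list(TESTGENE = rep(-3, 4)))
  bf <- bayes_factors(tr$fc, tr$refs, classifier_config(10, seed = 7),
                      genes = "TESTGENE")
  expect_equal(bf$n_guides, 4L)
  expect_equal(bf$bf, 4 * 4.5 / log(2), tolerance = 1.5 / 26)
})

test_that("a guide where the two densities are equal contributes zero", {
  ## every reference gene of both classes carries the same five values, so
  ## the two class densities coincide under any bootstrap resample and every
  ## log ratio is exactly zero
  refs <- ref_fixture(20, 20)
  vals <- c(-2, -1, 0, 1, 2)
  gene <- c(rep(refs$essentials, each = 5), rep(refs$nonessentials, each = 5),
            rep("PROBE", 2))
  fcv <- c(rep(vals, 40), -1.3, 0.7)
  names(gene) <- names(fcv) <- sprintf("g%04d", seq_along(gene))
  bf <- bayes_factors(fc_fixture(fcv, gene), refs,
                      classifier_config(5, seed = 1), genes = "PROBE")
  expect_equal(bf$bf, 0, tolerance = 1e-9)
})

test_that("BF is additive over guides and monotone toward the essential mode", {
  tr <- normal_training_fc(n_ref = 25L, guides_per_ref = 60L, mu_ess = -3,
                           extra = list(ONE = -2, FOUR = rep(-2, 4),
                                        SHIFTED = rep(-2.5, 4)))
  cfg <- classifier_config(8, seed = 21)
  bf <- bayes_factors(tr$fc, tr$refs, cfg, genes = c("ONE", "FOUR", "SHIFTED"))
  b <- setNames(bf$bf, bf$gene)
  ## additivity: four identical guides = 4x one guide (same training KDE)
  expect_equal(unname(b["FOUR"]), 4 * unname(b["ONE"]), tolerance = 1e-9)
  ## monotonicity: shifting fc toward the essential mode raises the BF
  expect_gt(b["SHIFTED"], b["FOUR"])
})

test_that("bayes_factors enforces its reference-coverage precondition", {
  tr <- normal_training_fc(n_ref = 10L, guides_per_ref = 20L)
  expect_error(bayes_factors(tr$fc, tr$refs, classifier_config(2, seed = 1)),
               ">=20 reference genes")
})

test_that("Bayes Factors are deterministic given the seed", {
  tr <- normal_training_fc(n_ref = 22L, guides_per_ref = 30L,
                           extra = list(PROBE = c(-1, -2)))
  cfg <- classifier_config(6, seed = 99)
  b1 <- bayes_factors(tr$fc, tr$refs, cfg, genes = "PROBE")
  b2 <- bayes_factors(tr$fc, tr$refs, cfg, genes = "PROBE")
  expect_identical(b1, b2)
  b3 <- bayes_factors(tr$fc, tr$refs, classifier_config(6, seed = 100),
                      genes = "PROBE")
  expect_false(identical(b1$bf, b3$bf))
})

test_that("precision-recall reproduces hand-counted curves", {
  refs <- reference_sets(c("E1", "E2", "E3"), c("N1", "N2"))
  ## perfect separation: precision 1 at every cutoff reaching only essentials
  bf <- c(E1 = 10, E2 = 9, E3 = 8, N1 = 2, N2 = 1)
  pr <- precision_recall(bf, refs)
  expect_equal(pr$precision[pr$bf_cutoff >= 8], rep(1, 3))
  expect_equal(pr$recall[pr$bf_cutoff == 8], 1)

  ## ranking E,N,E,E,N: at the cutoff including the first 4, precision 3/4
  bf2 <- c(E1 = 5, N1 = 4, E2 = 3, E3 = 2, N2 = 1)
  pr2 <- precision_recall(bf2, refs)
  row <- pr2[pr2$bf_cutoff == 2, ]
  expect_equal(row$precision, 3 / 4)
  expect_equal(row$recall, 1)
  expect_equal(row$fdr, 1 / 4)

  ## reversed perfect ranking: precision at full recall = |E|/(|E|+|N|)
  bf3 <- c(N1 = 10, N2 = 9, E1 = 3, E2 = 2, E3 = 1)
  pr3 <- precision_recall(bf3, refs)
  expect_equal(pr3$precision[pr3$recall == 1][1], 3 / 5)

  ## fdr = 1 - precision everywhere; recall non-increasing in the cutoff
  expect_equal(pr2$fdr, 1 - pr2$precision)
  expect_true(all(diff(pr2$recall) >= 0))  # rows are descending cutoffs

  expect_error(precision_recall(c(E1 = 1, E2 = 2), refs), "both reference")
})

test_that("posterior conversion matches the worked prior arithmetic", {
  ## prior 10% essential: log2(0.1/0.9) ~ -3.17
  p3 <- bf_to_posterior(3, 0.1)
  expect_equal(p3$posterior_log2_odds, 3 + log2(1 / 9), tolerance = 1e-12)
  expect_equal(p3$posterior_log2_odds, -0.170, tolerance = 1e-3)
  expect_equal(p3$posterior_probability, 0.4706, tolerance = 1e-3)
  ## rounds to the headline 50%
  expect_equal(round(p3$posterior_probability * 100 / 10) * 10, 50)

  p6 <- bf_to_posterior(6, 0.1)
  expect_equal(p6$posterior_log2_odds, 2.830, tolerance = 1e-3)
  expect_equal(round(p6$posterior_log2_odds), 3)
  expect_equal(p6$posterior_probability, 0.877, tolerance = 1e-3)
  expect_equal(round(p6$posterior_probability * 100 / 10) * 10, 90)

  p0 <- bf_to_posterior(0, 0.5)
  expect_equal(p0$posterior_log2_odds, 0)
  expect_equal(p0$posterior_probability, 0.5)
})

test_that("posterior conversion is strictly increasing and round-trips", {
  bfs <- seq(-10, 10, by = 0.5)
  post <- bf_to_posterior(bfs, 0.1)
  expect_true(all(diff(post$posterior_probability) > 0))
  priors <- c(0.05, 0.1, 0.3, 0.6)
  probs <- vapply(priors, function(p)
    bf_to_posterior(2, p)$posterior_probability, numeric(1))
  expect_true(all(diff(probs) > 0))
  ## odds -> probability -> odds identity
  odds <- post$posterior_log2_odds
  back <- log2(post$posterior_probability / (1 - post$posterior_probability))
  expect_equal(back, odds, tolerance = 1e-12)
})

test_that("core-essential calling applies the assayed/eligible/hit-fraction rule", {
  screens <- sprintf("S%02d", 1:12)
  fdr <- setNames(rep(0.02, 12), screens)
  mk <- function(n_assayed, n_hit) {
    bf <- rep(NA_real_, 12)
    bf[seq_len(n_assayed)] <- c(rep(10, n_hit), rep(1, n_assayed - n_hit))
    ng <- ifelse(is.na(bf), 0L, 4L)
    list(bf = bf, ng = ng)
  }
  rows <- list(A = mk(7, 6),    # assayed 7, essential 6 -> core
               B = mk(12, 10),  # assayed 12, essential 10 -> needs 11, NOT core
               C = mk(12, 11),  # assayed 12, essential 11 -> core
               D = mk(6, 6))    # assayed 6 -> not eligible
  bfm <- do.call(rbind, lapply(rows, `[[`, "bf"))
  ngm <- do.call(rbind, lapply(rows, `[[`, "ng"))
  dimnames(bfm) <- dimnames(ngm) <- list(names(rows), screens)
  res <- call_core_essentials(bayes_factor_table(bfm, ngm), fdr)
  expect_setequal(res$core, c("A", "C"))
  rep <- res$report
  expect_false(rep$eligible[rep$gene == "D"])
  expect_equal(rep$required_calls[rep$gene == "B"], 11)
  expect_equal(rep$required_calls[rep$gene == "A"], 6)

  ## a high-BF call in a screen failing the FDR gate does not count
  fdr_bad <- fdr
  fdr_bad["S01"] <- 0.10
  res_bad <- call_core_essentials(bayes_factor_table(bfm, ngm), fdr_bad)
  expect_false("A" %in% res_bad$core)  # loses one of its 6 required calls
})

test_that("the 85% ceiling rule means all-but-one for 7 to 12 assayed screens", {
  rule <- core_set_rule()
  for (n in 7:12) {
    expect_equal(ceiling(rule$hit_fraction * n), n - 1L)
  }
})

test_that("a gene at BF 6.2 in a screen with 2% FDR is called essential under the strict rule", {
  screens <- sprintf("S%02d", 1:7)
  bfm <- matrix(6.2, 1, 7, dimnames = list("GENE", screens))
  ngm <- matrix(4L, 1, 7, dimnames = list("GENE", screens))
  res <- call_core_essentials(bayes_factor_table(bfm, ngm),
                              setNames(rep(0.02, 7), screens))
  expect_equal(res$report$essential_calls, 7)
  expect_true("GENE" %in% res$core)
})

test_that("panel BF matrix TSV round-trips into the core-set caller", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "panel.tsv")
  screens <- sprintf("S%d", 1:7)
  bfm <- matrix(c(rep(8, 7), rep(NA, 7)), nrow = 2, byrow = TRUE,
                dimnames = list(c("HIT", "EMPTY"), screens))
  df <- data.frame(GENE = rownames(bfm), bfm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bft <- read_bf_matrix(path)
  expect_equal(bft$n_guides["EMPTY", ], setNames(rep(0L, 7), screens))
  res <- call_core_essentials(bft, setNames(rep(0.01, 7), screens))
  expect_equal(res$core, "HIT")
})
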