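#' Fraction of active guides
#'
#' A library/screen quality metric: among guides targeting reference
#' essential genes, the fraction whose (replicate-averaged) fold-change
#' lies below the 5th percentile of the fold-changes of guides targeting
#' reference nonessential genes. Percentiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7).
#'
#' @param fc a [foldchange_matrix()].
#' @param refs a [reference_sets()]; at least 20 nonessential-targeting
#'   guides must be retained.
#' @param percentile nonessential percentile defining the activity
#'   threshold (default 5).
#' @return list with `threshold_fc`, `n_active`, `n_total_essential_guides`,
#'   `fraction_active`.
#' @export
fraction_active_guides <- function(fc, refs, percentile = 5) {
  stopifnot(inherits(fc, "FoldchangeMatrix"), inherits(refs, "ReferenceSets"))
  mfc <- rowMeans(fc$fc, na.rm = TRUE)
  non <- mfc[fc$gene %in% refs$nonessentials & is.finite(mfc)]
  ess <- mfc[fc$gene %in% refs$essentials & is.finite(mfc)]
  if (length(non) < 20L) {
    stop(sprintf("need >=20 retained nonessential-targeting guides (have %d)",
                 length(non)))
  }
  if (!length(ess)) stop("no essential-targeting guides retained")
  thr <- unname(quantile(non, percentile / 100, type = 7))
  list(threshold_fc = thr,
       n_active = sum(ess < thr),
       n_total_essential_guides = length(ess),
       fraction_active = sum(ess < thr) / length(ess))
}

## hits at the spec'd rule: BF above threshold at per-gene FDR below limit
count_hits <- function(bf, refs, bf_min, fdr_max, core) {
  pr <- precision_recall(bf, refs)
  bfv <- as_bf_vector(bf)
  gene_fdr <- fdr_at_bf(pr, bfv)
  hit <- bfv > bf_min & gene_fdr < fdr_max
  core_present <- intersect(core, names(bfv))
  list(n_hits = sum(hit),
       fraction_core_recovered = if (length(core_present))
         sum(names(bfv)[hit] %in% core_present) / length(core_present)
       else NA_real_)
}

#' Guides-per-gene subsampling study
#'
#' For each `k` in `k_range` and each of `n_iter` iterations, `k` guides
#' per gene are sampled without replacement from the readcount matrix, the
#' fold-change and Bayes Factor analysis is rerun on the subset, and hits
#' are counted at the rule (default BF > 3 at FDR < 5%), together with the
#' fraction of a supplied core-essential set recovered. Genes with fewer
#' than `k` guides are skipped and logged.
#'
#' @param rc a [readcount_matrix()].
#' @param refs a [reference_sets()] used for BF training and FDR.
#' @param core character vector of core essential genes to track recovery.
#' @param k_range guides-per-gene values (default 2:7).
#' @param n_iter iterations per `k` (default 10).
#' @param rule list with `bf_min` (default 3) and `fdr_max` (default 0.05).
#' @param params a [norm_params()].
#' @param cfg a [classifier_config()] used for every BF run.
#' @param seed seed for the guide sampling.
#' @return list with `results` (one row per k x iteration: k, iteration,
#'   fraction_core_recovered, n_hits), `summary` (mean and SD per k), and
#'   `skipped` (genes with too few guides, per k).
#' @export
subsample_guides <- function(rc, refs, core, k_range = 2:7, n_iter = 10,
                             rule = list(bf_min = 3, fdr_max = 0.05),
                             params = norm_params(),
                             cfg = classifier_config(), seed = cfg$seed) {
  stopifnot(inherits(rc, "ReadcountMatrix"))
  guides_by_gene <- split(rownames(rc$counts), unname(rc$gene))
  res <- list()
  skipped <- list()
  withr::with_seed(seed, {
    for (k in k_range) {
      sizes <- vapply(guides_by_gene, length, integer(1L))
      usable <- names(guides_by_gene)[sizes >= k]
      skip <- names(guides_by_gene)[sizes < k]
      if (length(skip)) skipped[[as.character(k)]] <- skip
      if (!length(usable)) stop(sprintf("no gene has >=%d guides", k))
      for (it in seq_len(n_iter)) {
        take <- unlist(lapply(guides_by_gene[usable], function(g) {
          if (length(g) == k) g else sample(g, k)
        }), use.names = FALSE)
        sub <- readcount_matrix(rc$counts[take, , drop = FALSE],
                                rc$gene[take],
                                setNames(rc$samples$role, rc$samples$sample))
        fc <- compute_foldchange(sub, params)
        bf <- bayes_factors(fc, refs, cfg)
        h <- count_hits(bf, refs, rule$bf_min, rule$fdr_max, core)
        res[[length(res) + 1L]] <- data.frame(
          k = k, iteration = it,
          fraction_core_recovered = h$fraction_core_recovered,
          n_hits = h$n_hits)
      }
    }
  })
  results <- do.call(rbind, res)
  summary <- do.call(rbind, lapply(split(results, results$k), function(d) {
    data.frame(k = d$k[1L],
               mean_fraction_core = mean(d$fraction_core_recovered),
               sd_fraction_core = sd(d$fraction_core_recovered),
               mean_hits = mean(d$n_hits), sd_hits = sd(d$n_hits),
               n_iterations = nrow(d))
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary, skipped = skipped)
}

#' Replicate subsampling study
#'
#' For a screen with exactly three endpoint replicates, runs the Bayes
#' Factor analysis on each replicate alone, on the three pairs, and on all
#' three together (seven analyses), reporting hits and core recovery for
#' each combination.
#'
#' @param fc a [foldchange_matrix()] with exactly 3 replicate columns.
#' @inheritParams subsample_guides
#' @return data.frame with one row per combination: `label`,
#'   `n_replicates`, `fraction_core_recovered`, `n_hits`.
#' @export
subsample_replicates <- function(fc, refs, core,
                                 rule = list(bf_min = 3, fdr_max = 0.05),
                                 cfg = classifier_config()) {
  stopifnot(inherits(fc, "FoldchangeMatrix"))
  if (ncol(fc$fc) != 3L) {
    stop(sprintf("replicate subsampling requires exactly 3 replicates (have %d)",
                 ncol(fc$fc)))
  }
  combos <- c(lapply(1:3, identity), list(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
              list(1:3))
  out <- lapply(combos, function(idx) {
    sub <- foldchange_matrix(fc$fc[, idx, drop = FALSE], fc$gene)
    bf <- bayes_factors(sub, refs, cfg)
    h <- count_hits(bf, refs, rule$bf_min, rule$fdr_max, core)
    data.frame(label = paste(colnames(fc$fc)[idx], collapse = "+"),
               n_replicates = length(idx),
               fraction_core_recovered = h$fraction_core_recovered,
               n_hits = h$n_hits, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare nontargeting controls with nonessential-targeting guides
#'
#' Compares the replicate-averaged fold-change distribution of nontargeting
#' control guides with that of guides targeting reference nonessential
#' genes, by two-sided Welch (unequal-variance) t-test.
#'
#' @param fc a [foldchange_matrix()].
#' @param nontargeting character vector of nontargeting guide ids (or a
#'   control gene label present in the guide-to-gene map).
#' @param refs a [reference_sets()].
#' @return list with group sizes and means, the mean difference
#'   (nontargeting minus nonessential), `p_value`, and `degenerate`
#'   (TRUE when the test is undefined, e.g. zero variance in both groups).
#' @export
control_comparison <- function(fc, nontargeting, refs) {
  stopifnot(inherits(fc, "FoldchangeMatrix"))
  mfc <- rowMeans(fc$fc, na.rm = TRUE)
  nt_ids <- if (length(nontargeting) == 1L &&
                nontargeting %in% fc$gene &&
                !nontargeting %in% names(mfc)) {
    names(mfc)[fc$gene == nontargeting]
  } else intersect(nontargeting, names(mfc))
  nt <- mfc[nt_ids]
  non <- mfc[fc$gene %in% refs$nonessentials]
  if (!length(nt) || !length(non)) {
    stop("both control populations must be non-empty")
  }
  tt <- tryCatch(t.test(nt, non, var.equal = FALSE), error = function(e) NULL)
  list(n_nontargeting = length(nt), n_nonessential = length(non),
       mean_nontargeting = mean(nt), mean_nonessential = mean(non),
       mean_difference = mean(nt) - mean(non),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       degenerate = is.null(tt))
}
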