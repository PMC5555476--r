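#' Reference essential / nonessential gene sets
#'
#' @param essentials character vector of reference essential gene symbols.
#' @param nonessentials character vector of reference nonessential gene
#'   symbols. The two sets must be disjoint and non-empty.
#' @return a `ReferenceSets` list.
#' @export
reference_sets <- function(essentials, nonessentials) {
  essentials <- unique(as.character(essentials))
  nonessentials <- unique(as.character(nonessentials))
  if (!length(essentials) || !length(nonessentials)) {
    stop("both reference sets must be non-empty")
  }
  ov <- intersect(essentials, nonessentials)
  if (length(ov)) {
    stop(sprintf("reference sets overlap: %s", paste(head(ov, 3), collapse = ", ")))
  }
  structure(list(essentials = essentials, nonessentials = nonessentials),
            class = "ReferenceSets")
}

#' Read a gene list (one symbol per line)
#'
#' @param path plain-text file, one gene symbol per line; blank lines ignored.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("gene list not found: %s", path))
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Configuration for the Bayes Factor classifier
#'
#' The classifier follows the BAGEL family of essentiality callers: guide
#' fold-changes of reference essential and nonessential genes train two
#' Gaussian kernel densities, and a gene's Bayes Factor is the summed log2
#' likelihood ratio of its guide fold-changes under the two densities,
#' averaged over bootstrap resamples of the reference genes.
#'
#' @param bootstrap_iterations number of bootstrap iterations (default 1000).
#' @param kde_bandwidth_rule bandwidth selector; `"scott"` (the default)
#'   uses [stats::bw.nrd()].
#' @param fc_eval_bounds optional length-2 numeric clamp range for density
#'   evaluation; by default the range of the training fold-changes of the
#'   current iteration is used.
#' @param seed integer seed making the bootstrap deterministic.
#' @return a `ClassifierConfig` list.
#' @export
classifier_config <- function(bootstrap_iterations = 1000,
                              kde_bandwidth_rule = "scott",
                              fc_eval_bounds = NULL,
                              seed = 1934) {
  stopifnot(bootstrap_iterations >= 1)
  kde_bandwidth_rule <- match.arg(kde_bandwidth_rule, c("scott", "silverman"))
  structure(list(bootstrap_iterations = as.integer(bootstrap_iterations),
                 kde_bandwidth_rule = kde_bandwidth_rule,
                 fc_eval_bounds = fc_eval_bounds,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

## Gaussian KDE evaluated at x, chunked to bound memory.
kde_density <- function(x, train, bw, floor = 1e-12) {
  n <- length(x)
  out <- numeric(n)
  chunk <- max(1L, floor(5e6 / length(train)))
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1L)
    out[i0:i1] <- rowMeans(dnorm(outer(x[i0:i1], train, "-"), sd = bw))
  }
  pmax(out, floor)
}

kde_bandwidth <- function(train, rule) {
  if (length(train) < 2L || sd(train) == 0) {
    stop("training fold-changes are degenerate (need >=2 distinct values)")
  }
  switch(rule,
         scott = stats::bw.nrd(train),
         silverman = stats::bw.nrd0(train))
}

#' Gene-level essentiality Bayes Factors
#'
#' For each gene, the Bayes Factor (BF) is the sum, over its retained
#' guide/replicate fold-change values, of
#' `log2(density_essential(fc) / density_nonessential(fc))`, where the two
#' densities are Gaussian kernel density estimates trained on the guide
#' fold-changes of the reference essential and nonessential genes. Each
#' bootstrap iteration resamples the reference genes (not guides) with
#' replacement, and the mean BF over iterations is reported. Density
#' evaluation points are clamped to the training fold-change range and the
#' densities floored at 1e-12 so log ratios stay finite.
#'
#' @param fc a [foldchange_matrix()].
#' @param refs a [reference_sets()] object. At least 20 reference genes of
#'   each class must have retained guides.
#' @param cfg a [classifier_config()].
#' @param genes optional character vector restricting the genes scored
#'   (reference genes always contribute to training regardless).
#' @return data.frame with columns `gene`, `bf`, `n_guides` (retained guides
#'   per gene). Genes with zero retained guides are absent.
#' @export
bayes_factors <- function(fc, refs, cfg = classifier_config(), genes = NULL) {
  stopifnot(inherits(fc, "FoldchangeMatrix"), inherits(refs, "ReferenceSets"))
  gene_of <- fc$gene
  vals <- fc$fc
  ## flatten guide x replicate values, tracking gene of each value
  flat <- as.vector(vals)
  flat_gene <- rep(unname(gene_of), times = ncol(vals))
  ok <- is.finite(flat)
  flat <- flat[ok]
  flat_gene <- flat_gene[ok]

  by_gene <- split(flat, flat_gene)
  ess_genes <- intersect(refs$essentials, names(by_gene))
  non_genes <- intersect(refs$nonessentials, names(by_gene))
  if (length(ess_genes) < 20L || length(non_genes) < 20L) {
    stop(sprintf(paste0("need >=20 reference genes of each class with ",
                        "retained guides (have %d essential, %d nonessential)"),
                 length(ess_genes), length(non_genes)))
  }

  out_genes <- if (is.null(genes)) names(by_gene) else
    intersect(genes, names(by_gene))
  if (!length(out_genes)) stop("no requested gene has retained guides")
  eval_idx <- flat_gene %in% out_genes
  x_all <- flat[eval_idx]
  x_gene <- factor(flat_gene[eval_idx], levels = out_genes)

  bf_sum <- setNames(numeric(length(out_genes)), out_genes)
  withr::with_seed(cfg$seed, {
    for (it in seq_len(cfg$bootstrap_iterations)) {
      tr_e <- unlist(by_gene[sample(ess_genes, replace = TRUE)],
                     use.names = FALSE)
      tr_n <- unlist(by_gene[sample(non_genes, replace = TRUE)],
                     use.names = FALSE)
      bounds <- cfg$fc_eval_bounds
      if (is.null(bounds)) bounds <- range(c(tr_e, tr_n))
      x <- pmin(pmax(x_all, bounds[1L]), bounds[2L])
      de <- kde_density(x, tr_e, kde_bandwidth(tr_e, cfg$kde_bandwidth_rule))
      dn <- kde_density(x, tr_n, kde_bandwidth(tr_n, cfg$kde_bandwidth_rule))
      contrib <- log2(de / dn)
      s <- rowsum(contrib, x_gene)
      bf_sum[rownames(s)] <- bf_sum[rownames(s)] + s[, 1L]
    }
  })

  n_guides <- vapply(split(rownames(vals), unname(gene_of))[out_genes],
                     length, integer(1L))
  data.frame(gene = out_genes,
             bf = unname(bf_sum / cfg$bootstrap_iterations),
             n_guides = unname(n_guides),
             stringsAsFactors = FALSE)
}

as_bf_vector <- function(bf) {
  if (is.data.frame(bf)) setNames(bf$bf, bf$gene) else bf
}

#' Precision-recall curve over reference genes
#'
#' Genes are ranked by descending Bayes Factor; at each distinct cutoff,
#' precision and recall are computed over the reference genes only
#' (`precision = TP/(TP+FP)`, `recall = TP / |essentials scored|`,
#' `fdr = 1 - precision`).
#'
#' @param bf named numeric vector of Bayes Factors, or the data.frame
#'   returned by [bayes_factors()].
#' @param refs a [reference_sets()] object; both classes must intersect the
#'   scored genes.
#' @return data.frame with columns `bf_cutoff`, `precision`, `recall`,
#'   `fdr`, ordered by descending cutoff.
#' @export
precision_recall <- function(bf, refs) {
  bfv <- as_bf_vector(bf)
  ess <- intersect(names(bfv), refs$essentials)
  non <- intersect(names(bfv), refs$nonessentials)
  if (!length(ess) || !length(non)) {
    stop("scored genes must include both reference classes")
  }
  cut <- sort(unique(bfv[c(ess, non)]), decreasing = TRUE)
  tp <- vapply(cut, function(t) sum(bfv[ess] >= t), numeric(1L))
  fp <- vapply(cut, function(t) sum(bfv[non] >= t), numeric(1L))
  precision <- tp / (tp + fp)
  data.frame(bf_cutoff = cut, precision = precision,
             recall = tp / length(ess), fdr = 1 - precision,
             row.names = NULL)
}

#' FDR read off a precision-recall curve at a BF threshold
#'
#' Returns `1 - precision` at the smallest curve cutoff that is `>=` the
#' threshold; thresholds above the top of the curve use the highest cutoff.
#'
#' @param pr curve from [precision_recall()].
#' @param bf numeric vector of BF thresholds.
#' @return numeric vector of FDR values.
#' @export
fdr_at_bf <- function(pr, bf) {
  vapply(bf, function(b) {
    i <- which(pr$bf_cutoff >= b)
    if (length(i)) pr$fdr[max(i)] else pr$fdr[1L]
  }, numeric(1L))
}

#' Posterior essentiality odds and probability from a Bayes Factor
#'
#' The BF is a log2 likelihood ratio; multiplying the implied odds by the
#' prior odds `p/(1-p)` gives posterior odds. With the default prior of 10%
#' essential genes per cell line, a BF of 3 corresponds to posterior log2
#' odds near 0 (probability ~50%) and a BF of 6 to posterior log2 odds near
#' 3 (probability ~90%).
#'
#' @param bf numeric vector of Bayes Factors (log2 units).
#' @param p_essential prior probability that a gene is essential
#'   (default 0.1); must lie in (0, 1).
#' @return data.frame with columns `bf`, `posterior_log2_odds`,
#'   `posterior_probability`.
#' @export
bf_to_posterior <- function(bf, p_essential = 0.1) {
  stopifnot(p_essential > 0, p_essential < 1)
  odds <- bf + log2(p_essential / (1 - p_essential))
  data.frame(bf = bf,
             posterior_log2_odds = odds,
             posterior_probability = 2^odds / (1 + 2^odds))
}

#' Panel of Bayes Factors across screens
#'
#' @param bf numeric matrix of Bayes Factors, genes in rows, screens in
#'   columns; `NA` marks a gene not assayed in that screen.
#' @param n_guides integer matrix of the same shape giving the number of
#'   guides assayed per (gene, screen); 0 or `NA` where absent.
#' @return a `BayesFactorTable` list.
#' @export
bayes_factor_table <- function(bf, n_guides) {
  bf <- as.matrix(bf)
  n_guides <- as.matrix(n_guides)
  stopifnot(identical(dim(bf), dim(n_guides)))
  if (is.null(rownames(bf)) || is.null(colnames(bf))) {
    stop("bf matrix needs gene rownames and screen colnames")
  }
  n_guides[is.na(n_guides)] <- 0L
  if (any(!is.na(bf) & n_guides < 1L)) {
    stop("bf present for a (gene, screen) with no assayed guides")
  }
  structure(list(bf = bf, n_guides = n_guides,
                 genes = rownames(bf), screens = colnames(bf)),
            class = "BayesFactorTable")
}

#' Core-essential calling rule
#'
#' @param bf_threshold strict BF threshold for an essential call (default 6).
#' @param fdr_threshold maximum screen-level FDR at the BF threshold for the
#'   screen's calls to count (default 0.03).
#' @param min_guides_assayed guides needed for a gene to count as assayed in
#'   a screen (default 3).
#' @param min_screens_assayed screens a gene must be assayed in to be
#'   eligible (default 7).
#' @param hit_fraction fraction of assayed screens in which the gene must be
#'   called essential (default 0.85; the required count is the ceiling of
#'   `hit_fraction * screens_assayed`, i.e. "all but one" for 7-12 screens).
#' @return a `CoreSetRule` list.
#' @export
core_set_rule <- function(bf_threshold = 6, fdr_threshold = 0.03,
                          min_guides_assayed = 3, min_screens_assayed = 7,
                          hit_fraction = 0.85) {
  stopifnot(bf_threshold > 0, fdr_threshold > 0, min_guides_assayed > 0,
            min_screens_assayed > 0, hit_fraction > 0, hit_fraction <= 1)
  structure(list(bf_threshold = bf_threshold, fdr_threshold = fdr_threshold,
                 min_guides_assayed = min_guides_assayed,
                 min_screens_assayed = min_screens_assayed,
                 hit_fraction = hit_fraction),
            class = "CoreSetRule")
}

#' Call core essential genes across a panel of screens
#'
#' A gene counts as assayed in a screen if it has at least
#' `min_guides_assayed` guides there, and is eligible if assayed in at least
#' `min_screens_assayed` screens. It is called essential in a screen if its
#' BF meets `bf_threshold` and that screen's FDR at the threshold is within
#' `fdr_threshold`. Eligible genes essential in at least
#' `ceiling(hit_fraction * screens_assayed)` of their assayed screens form
#' the core set.
#'
#' @param bft a [bayes_factor_table()].
#' @param per_screen_fdr named numeric vector: each screen's FDR at
#'   `rule$bf_threshold` (see [fdr_at_bf()]).
#' @param rule a [core_set_rule()].
#' @return list with `core` (character vector of core genes) and `report`
#'   (per-gene data.frame: screens assayed, essential calls, required calls,
#'   eligibility, core status).
#' @export
call_core_essentials <- function(bft, per_screen_fdr, rule = core_set_rule()) {
  stopifnot(inherits(bft, "BayesFactorTable"), inherits(rule, "CoreSetRule"))
  if (ncol(bft$bf) < rule$min_screens_assayed) {
    stop(sprintf("panel has %d screens; rule requires >=%d",
                 ncol(bft$bf), rule$min_screens_assayed))
  }
  miss <- setdiff(bft$screens, names(per_screen_fdr))
  if (length(miss)) {
    stop(sprintf("per_screen_fdr missing screen(s): %s",
                 paste(miss, collapse = ", ")))
  }
  assayed <- bft$n_guides >= rule$min_guides_assayed
  screen_ok <- per_screen_fdr[bft$screens] <= rule$fdr_threshold
  called <- assayed & !is.na(bft$bf) & bft$bf >= rule$bf_threshold &
    matrix(screen_ok, nrow = nrow(bft$bf), ncol = ncol(bft$bf), byrow = TRUE)
  n_assayed <- rowSums(assayed)
  n_called <- rowSums(called)
  required <- ceiling(rule$hit_fraction * n_assayed)
  eligible <- n_assayed >= rule$min_screens_assayed
  core <- eligible & n_called >= required
  report <- data.frame(gene = bft$genes,
                       screens_assayed = n_assayed,
                       essential_calls = n_called,
                       required_calls = required,
                       eligible = eligible,
                       core = core,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(core = bft$genes[core], report = report)
}

#' Write per-screen Bayes Factors
#'
#' @param bf data.frame from [bayes_factors()].
#' @param path output TSV path (columns GENE, BF, NUM_GUIDES).
#' @export
write_bf <- function(bf, path) {
  write.table(data.frame(GENE = bf$gene, BF = bf$bf, NUM_GUIDES = bf$n_guides),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel BF matrix TSV (genes x screens; empty cell = not assayed)
#'
#' @param path TSV with a GENE column then one column per screen.
#' @param n_guides optional TSV of the same shape with assayed-guide counts;
#'   if omitted, every non-empty BF cell is treated as assayed with
#'   `default_guides` guides.
#' @param default_guides guide count assumed when `n_guides` is missing.
#' @return a [bayes_factor_table()].
#' @export
read_bf_matrix <- function(path, n_guides = NULL, default_guides = 4L) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (is.null(n_guides)) {
    ng <- ifelse(is.na(m), 0L, default_guides)
  } else {
    dg <- read.delim(n_guides, header = TRUE, sep = "\t", check.names = FALSE)
    ng <- as.matrix(dg[, -1L, drop = FALSE])
    rownames(ng) <- dg[[1L]]
    ng <- ng[rownames(m), colnames(m), drop = FALSE]
  }
  bayes_factor_table(m, ng)
}
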