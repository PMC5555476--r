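## Shared in-code fixtures for the test suite. Everything is generated
## programmatically; seeds are fixed so all tests are deterministic.

## A tiny readcount TSV on disk; returns its path.
write_toy_counts <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  writeLines(c(
    "GUIDE\tGENE\tT0\tEND",
    "g1\tGENEA\t100\t100",
    "g2\tGENEA\t100\t0",
    "g3\tGENEB\t50\t200"), path)
  path
}

toy_roles <- c(T0 = "t0_control", END = "endpoint")

## FoldchangeMatrix built directly from per-guide values (single replicate
## unless fc is a matrix).
fc_fixture <- function(fc, gene) {
  if (!is.matrix(fc)) fc <- matrix(fc, ncol = 1L,
                                   dimnames = list(names(fc), "R1"))
  foldchange_matrix(fc, gene)
}

## Reference sets with n synthetic gene symbols per class.
ref_fixture <- function(n_ess = 25L, n_non = 25L) {
  reference_sets(sprintf("ESS%03d", seq_len(n_ess)),
                 sprintf("NON%03d", seq_len(n_non)))
}

## FoldchangeMatrix whose reference genes carry draws from two normals:
## essentials ~ N(mu_ess, 1), nonessentials ~ N(0, 1). Extra genes can be
## appended with fixed fc values for closed-form checks.
normal_training_fc <- function(n_ref = 25L, guides_per_ref = 100L,
                               mu_ess = -3, extra = NULL, seed = 42L) {
  withr::with_seed(seed, {
    refs <- ref_fixture(n_ref, n_ref)
    gene <- c(rep(refs$essentials, each = guides_per_ref),
              rep(refs$nonessentials, each = guides_per_ref))
    vals <- c(stats::rnorm(n_ref * guides_per_ref, mu_ess, 1),
              stats::rnorm(n_ref * guides_per_ref, 0, 1))
    if (!is.null(extra)) {
      gene <- c(gene, rep(names(extra), lengths(extra)))
      vals <- c(vals, unlist(extra, use.names = FALSE))
    }
    ids <- sprintf("guide%05d", seq_along(vals))
    list(fc = fc_fixture(stats::setNames(vals, ids), stats::setNames(gene, ids)),
         refs = refs)
  })
}

## Six-guide gene fold-change sample for score-table derivation: guide ids
## are the sequences themselves.
six_guide_sample <- function(seqs_best, seqs_worst, gene = "CEG1") {
  stopifnot(length(seqs_best) == 3L, length(seqs_worst) == 3L)
  seqs <- c(seqs_best, seqs_worst)
  fc <- stats::setNames(c(-3, -2.5, -2, -0.2, -0.1, 0), seqs)
  fc_fixture(fc, stats::setNames(rep(gene, 6L), seqs))
}

## Random 20-mer helper with optional fixed characters (named by position).
rand20 <- function(fixed = NULL) {
  ch <- sample(c("A", "C", "G", "T"), 20L, replace = TRUE)
  if (!is.null(fixed)) ch[as.integer(names(fixed))] <- fixed
  paste(ch, collapse = "")
}

## A small planted score signature of the delta-frequency family:
## column-centered, scaled to extreme 1.
planted_signature <- function(seed = 5L, sd = 0.5) {
  withr::with_seed(seed, {
    w <- matrix(stats::rnorm(80, sd = sd), 4, 20,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    w <- sweep(w, 2, colMeans(w))
    score_table(w / max(abs(w)))
  })
}

## A panel of screens sharing one library and one essential set.
panel_fixture <- function(n_screens = 12L, n_genes = 300L,
                          guides_per_gene = 4L, replicates = 2L,
                          depth = 2e6, effect_size = 3, seed = 400L) {
  base <- make_screen(synth_screen_spec(
    n_genes = n_genes, guides_per_gene = guides_per_gene,
    replicates = replicates, depth = depth, effect_size = effect_size,
    seed = seed))
  lib <- base$truth$library
  ess <- base$truth$essential_genes
  screens <- lapply(seq_len(n_screens), function(s) {
    make_screen(synth_screen_spec(
      n_genes = n_genes, guides_per_gene = guides_per_gene,
      replicates = replicates, depth = depth, effect_size = effect_size,
      seed = seed + s), library = lib, essential_genes = ess)
  })
  list(library = lib, essential = ess,
       genes = unique(lib$gene), screens = screens)
}
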