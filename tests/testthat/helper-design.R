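## Independent brute-force oracles for the library-design tests. These scan
## every offset with plain substring arithmetic and deliberately share no
## code with the package's enumeration/classification path.

## Every (gene, strand, window start) whose SpCas9 cut bond falls inside a
## coding exon of that gene.
oracle_enumerate <- function(genome, models) {
  out <- list()
  for (m in models) {
    S <- genome[[m$chrom]]
    L <- nchar(S)
    for (p in 1:(L - 22L)) {
      if (substring(S, p + 21L, p + 22L) == "GG") {
        cut <- p + 16L
        inside <- any(cut >= m$exons$start & cut + 1L <= m$exons$end)
        if (inside) {
          out[[length(out) + 1L]] <- data.frame(
            gene = m$gene, strand = "+", start = p, cut_site = cut,
            stringsAsFactors = FALSE)
        }
      }
      if (substring(S, p, p + 1L) == "CC") {
        cut <- p + 5L
        inside <- any(cut >= m$exons$start & cut + 1L <= m$exons$end)
        if (inside) {
          out[[length(out) + 1L]] <- data.frame(
            gene = m$gene, strand = "-", start = p, cut_site = cut,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(gene = character(0),
                                      strand = character(0),
                                      start = integer(0),
                                      cut_site = integer(0)))
  do.call(rbind, out)
}

## Expected off-target class derived from the exhaustive oracle hits by
## straightforward interval bookkeeping.
oracle_classify <- function(protospacer, target_gene, genome, models,
                            max_mismatches = 2L) {
  hits <- oracle_offtargets(protospacer, genome, max_mismatches)
  bodies <- lapply(models, function(m)
    list(gene = m$gene, chrom = m$chrom, lo = m$body[1], hi = m$body[2]))
  in_target <- logical(nrow(hits))
  in_other <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (b in bodies) {
      if (hits$chrom[i] == b$chrom && hits$cut_site[i] >= b$lo &&
          hits$cut_site[i] + 1L <= b$hi) {
        if (b$gene == target_gene) in_target[i] <- TRUE else in_other[i] <- TRUE
      }
    }
  }
  if (any(in_other & !in_target)) return("excluded")
  n_t <- sum(in_target)
  n_i <- sum(!in_target & !in_other)
  if (n_i == 0L) {
    if (n_t >= 2L) "1" else "2"
  } else if (n_i <= 2L) "3" else if (n_i == 3L) "4" else "excluded"
}

## Minimal candidate table for selection tests.
cand_df <- function(gene, exon, score, rank, proto = NULL) {
  n <- length(gene)
  if (is.null(proto)) {
    proto <- vapply(seq_len(n), function(i) rand20(), character(1))
  }
  data.frame(guide_id = paste0("c", seq_len(n)), gene = gene, exon = exon,
             chrom = "chr1", strand = "+", start = seq_len(n) * 100L,
             cut_site = seq_len(n) * 100L + 16L, protospacer = proto,
             pam = "AGG", gc = 0.5, seq_score = score, rank = rank,
             stringsAsFactors = FALSE)
}
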