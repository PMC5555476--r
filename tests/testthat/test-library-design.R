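test_that("candidate enumeration agrees with the brute-force scan", {
  g <- make_genome(synth_genome_spec(chrom_length = 3000, n_genes = 2,
                                     exons_per_gene = 2, seed = 51))
  cands <- enumerate_candidates(g$genome, g$models)
  oracle <- oracle_enumerate(g$genome, g$models)
  key <- function(d) sort(paste(d$gene, d$strand, d$start))
  expect_identical(key(cands), key(oracle))
  ## recorded protospacers match the genome at the recorded coordinates
  fwd <- cands[cands$strand == "+", ]
  expect_equal(fwd$protospacer,
               unname(substring(g$genome[fwd$chrom], fwd$start,
                                fwd$start + 19)))
  expect_true(all(cands$pam %in% paste0(c("A", "C", "G", "T"), "GG")))
})

test_that("a PAM-free sequence yields no candidates", {
  genome <- c(chr1 = strrep("AT", 100))
  m <- gene_model("G1", "chr1", "+", data.frame(start = 20, end = 150))
  expect_equal(nrow(enumerate_candidates(genome, list(m))), 0L)
})

test_that("the cut site, not the PAM, must fall inside the coding exon", {
  ## all-A chromosome with one forward PAM: protospacer at 40..59, GG at
  ## 61..62, cut bond between 56 and 57
  S <- strrep("A", 200)
  substr(S, 61, 62) <- "GG"
  genome <- c(chr1 = S)
  inside <- gene_model("G1", "chr1", "+", data.frame(start = 30, end = 70))
  m_in <- enumerate_candidates(genome, list(inside))
  expect_equal(nrow(m_in), 1L)
  expect_equal(m_in$cut_site, 56L)
  expect_identical(key <- m_in$strand, "+")
  ## exon ending 2 bp before the cut bond: no candidate
  outside <- gene_model("G1", "chr1", "+", data.frame(start = 30, end = 54))
  expect_equal(nrow(enumerate_candidates(genome, list(outside))), 0L)
  ## oracle agrees in both cases
  expect_equal(nrow(oracle_enumerate(genome, list(inside))), 1L)
  expect_equal(nrow(oracle_enumerate(genome, list(outside))), 0L)

  bad <- gene_model("G1", "chr1", "+", data.frame(start = 150, end = 300))
  expect_error(enumerate_candidates(genome, list(bad)), "beyond")
})

test_that("sequence filters reject GC, homopolymer, restriction-site, and SNP violations", {
  protos <- c(gc_low = paste0(strrep("AT", 6), "GCGCGCGC"),    # 8/20 = 40% -> pass
              gc_35 = paste0(strrep("AT", 6), "GCGCGCGA"),     # 7/20 = 35% -> fail
              homop = paste0("TTTT", strrep("AC", 5), "GCGCGC"),
              resite = paste0("ACCGGT", strrep("AC", 4), "GCGCGC"),
              clean = strrep("ACGT", 5))
  cands <- data.frame(guide_id = names(protos), gene = "G1", exon = 1L,
                      chrom = "chr1", strand = "+",
                      start = c(100L, 200L, 300L, 400L, 500L),
                      cut_site = c(116L, 216L, 316L, 416L, 516L),
                      protospacer = unname(protos), pam = "AGG",
                      gc = gc_fraction <- (nchar(protos) -
                                             nchar(gsub("[GC]", "", protos))) / 20,
                      stringsAsFactors = FALSE)
  out <- apply_filters(cands, filter_config(),
                       snps = data.frame(chrom = "chr1", pos = 510L))
  expect_true(out$pass[out$guide_id == "gc_low"])
  expect_equal(out$reject_reason[out$guide_id == "gc_35"], "gc")
  expect_equal(out$reject_reason[out$guide_id == "homop"], "homopolymer")
  expect_equal(out$reject_reason[out$guide_id == "resite"], "restriction_site")
  ## SNP at position 510 overlaps the clean guide's protospacer (500..519)
  expect_equal(out$reject_reason[out$guide_id == "clean"], "snp")
  ## without the SNP the clean guide passes
  out2 <- apply_filters(cands, filter_config())
  expect_true(out2$pass[out2$guide_id == "clean"])
  ## a restriction site on the reverse strand is also caught
  rc_site <- data.frame(guide_id = "rc", gene = "G1", exon = 1L,
                        chrom = "chr1", strand = "+", start = 600L,
                        cut_site = 616L,
                        protospacer = paste0("GCAGGT", strrep("AC", 4),
                                             "GCGCGC"),  # revcomp(ACCTGC)
                        pam = "AGG", gc = 0.6, stringsAsFactors = FALSE)
  expect_equal(apply_filters(rc_site, filter_config())$reject_reason, "restriction_site")
})

test_that("off-target classification reproduces the worked class examples", {
  ## unique perfect hit, no off-target within 2 mismatches -> class 2
  g2 <- make_genome(synth_genome_spec(chrom_length = 4000, n_genes = 2,
                                      seed = 61))
  ot <- g2$truth$on_targets
  cand <- data.frame(gene = ot$gene, chrom = ot$chrom, strand = ot$strand,
                     start = ot$start, cut_site = ot$cut_site,
                     protospacer = ot$protospacer, pam = ot$pam,
                     stringsAsFactors = FALSE)
  cls <- classify_offtargets(cand, g2$genome, g2$models)
  expect_equal(cls$offtarget_class,
               vapply(seq_len(nrow(cand)), function(i)
                 oracle_classify(cand$protospacer[i], cand$gene[i],
                                 g2$genome, g2$models), character(1)))
  expect_true(all(cls$offtarget_class == "2"))

  ## target hit + two intergenic 2-mismatch sites -> class 3
  g3 <- make_genome(synth_genome_spec(chrom_length = 6000, n_genes = 2,
                                      offtargets_per_gene = 2,
                                      offtarget_mismatches = 2, seed = 62))
  ot3 <- g3$truth$on_targets[1, ]
  cls3 <- classify_offtargets(
    data.frame(gene = ot3$gene, chrom = ot3$chrom, strand = "+",
               start = ot3$start, cut_site = ot3$cut_site,
               protospacer = ot3$protospacer, pam = ot3$pam),
    g3$genome, g3$models)
  expect_equal(cls3$offtarget_class, "3")
  expect_equal(cls3$n_intergenic_offtargets, 2L)

  ## a near-match inside another gene's intron -> excluded
  g4 <- make_genome(synth_genome_spec(chrom_length = 6000, n_genes = 2,
                                      exons_per_gene = 3, intron_length = 80,
                                      offtargets_per_gene = 1,
                                      offtarget_genic = 1, seed = 63))
  ot4 <- g4$truth$on_targets[1, ]
  expect_true(g4$truth$offtargets$genic[1])
  cls4 <- classify_offtargets(
    data.frame(gene = ot4$gene, chrom = ot4$chrom, strand = "+",
               start = ot4$start, cut_site = ot4$cut_site,
               protospacer = ot4$protospacer, pam = ot4$pam),
    g4$genome, g4$models)
  expect_equal(cls4$offtarget_class, "excluded")
})

test_that("rank assignment follows the class/score tiers in order", {
  cands <- data.frame(offtarget_class = c("1", "4", "2", "1", "3", "2",
                                          "excluded", "4"),
                      seq_score = c(0.5, 0.9, 0.5, -0.5, 0.9, 0.85,
                                    0.9, 0.5))
  ranked <- assign_ranks(cands)
  expect_equal(ranked$rank,
               c(1L,   # class 1, score > 0
                 3L,   # class 4, score > 0.85 (rank 2 excludes class 4)
                 4L,   # class 2, score in [0, 0.85]
                 5L,   # class 1, score < 0 but >= -1
                 2L,   # class 3, score > 0.85
                 4L,   # boundary: 0.85 is not > 0.85
                 NA,   # excluded class never ranks
                 5L))  # class 4, mid score -> only rank 5 admits it
})

test_that("greedy selection prefers fresh exons, then score", {
  ## rank-2 candidates in 5 distinct exons -> 4 guides in 4 distinct exons
  withr::with_seed(70, {
    five <- cand_df(rep("G1", 5), exon = 1:5, score = c(5, 4, 3, 2, 1) / 5,
                    rank = 2L)
  })
  sel <- select_library(five)
  expect_equal(nrow(sel$guides), 4L)
  expect_equal(sort(sel$guides$exon), 1:4)

  ## zero ranked candidates -> untargeted
  withr::with_seed(71, none <- cand_df("G2", 1L, 0.5, NA_integer_))
  sel2 <- select_library(none)
  expect_equal(nrow(sel2$guides), 0L)
  expect_equal(sel2$untargeted, "G2")

  ## 6 candidates in one exon -> 4 guides by descending score
  withr::with_seed(72, {
    six <- cand_df(rep("G3", 6), exon = 1L,
                   score = c(0.9, 0.3, 0.7, 0.5, 0.8, 0.2), rank = 2L)
  })
  sel3 <- select_library(six)
  expect_equal(sel3$guides$seq_score, c(0.9, 0.8, 0.7, 0.5))
  expect_equal(sel3$guides$round, 1:4)

  ## exon preference is per round: a high-scoring guide in a covered exon
  ## loses to a fresh exon in the same rank
  withr::with_seed(73, {
    mix <- cand_df(rep("G4", 3), exon = c(1L, 1L, 2L),
                   score = c(0.9, 0.8, 0.1), rank = 2L)
  })
  sel4 <- select_library(mix, guides_per_gene = 2L)
  expect_equal(sel4$guides$exon, c(1L, 2L))
  expect_equal(sel4$guides$seq_score, c(0.9, 0.1))
})

test_that("selection respects rank order and logs duplicate protospacers across genes", {
  withr::with_seed(74, {
    shared <- rand20()
    cands <- rbind(
      cand_df("GA", 1L, 0.2, 5L, proto = shared),
      cand_df("GB", 1L, 0.9, 2L, proto = shared),
      cand_df("GB", 2L, 0.9, 2L))
  })
  sel <- select_library(cands, gene_order = c("GA", "GB"))
  ## GA appears first in gene order, so it keeps the shared protospacer
  expect_equal(sel$conflicts$kept_gene, "GA")
  expect_equal(sel$conflicts$dropped_gene, "GB")
  expect_false(any(duplicated(sel$guides$protospacer)))
  ## rank-2 guides are selected before rank-5 guides
  expect_equal(sel$guides$rank[sel$guides$gene == "GB"], 2L)
})

test_that("selected guides always satisfy their recorded rank's contract and quota", {
  withr::with_seed(75, {
    n <- 120L
    cands <- cand_df(sample(sprintf("G%02d", 1:8), n, replace = TRUE),
                     exon = sample(1:5, n, replace = TRUE),
                     score = round(runif(n, -1, 2), 3), rank = NA_integer_)
    cands$offtarget_class <- as.character(sample(1:4, n, replace = TRUE))
  })
  cands <- assign_ranks(cands)
  sel <- select_library(cands)
  rules <- rank_rules()
  expect_true(all(table(sel$guides$gene) <= 4L))
  for (i in seq_len(nrow(sel$guides))) {
    r <- rules[rules$rank == sel$guides$rank[i], ]
    expect_true(as.integer(sel$guides$offtarget_class[i]) %in% r$classes[[1]])
    lo_ok <- if (r$min_open) sel$guides$seq_score[i] > r$score_min else
      sel$guides$seq_score[i] >= r$score_min
    expect_true(lo_ok && sel$guides$seq_score[i] <= r$score_max)
  }
  ## byte-identical rerun
  expect_identical(sel, select_library(cands))
})

test_that("raising a gene's candidate scores never lowers a selected guide's rank", {
  withr::with_seed(76, {
    n <- 60L
    cands <- cand_df(rep("G1", n), exon = sample(1:6, n, replace = TRUE),
                     score = round(runif(n, -1, 1.2), 3), rank = NA_integer_)
    cands$offtarget_class <- as.character(sample(1:4, n, replace = TRUE))
  })
  before <- select_library(assign_ranks(cands))
  boosted <- cands
  boosted$seq_score <- pmin(boosted$seq_score + 0.6, 2)
  after <- select_library(assign_ranks(boosted))
  expect_lte(max(after$guides$rank), max(before$guides$rank))
})

test_that("the full design pipeline accounts for every selected guide and control", {
  g <- make_genome(synth_genome_spec(chrom_length = 6000, n_genes = 3,
                                     exons_per_gene = 2, snp_density = 0.001,
                                     seed = 80), dir = withr::local_tempdir())
  tbl <- planted_signature(seed = 81)
  controls <- data.frame(guide_id = sprintf("CTRL%02d", 1:5),
                         gene = "EGFP",
                         protospacer = replicate(5, rand20()),
                         stringsAsFactors = FALSE)
  res <- design_library(g$paths$fasta, g$paths$gtf, tbl, snps = g$paths$vcf,
                        controls = controls)
  expect_s3_class(res$design, "LibraryDesign")
  expect_equal(res$summary$library_size,
               res$summary$n_selected + res$summary$n_controls)
  expect_equal(res$summary$n_selected, sum(res$summary$per_rank$n_added))
  expect_lte(res$summary$n_selected, 4L * 3L)
  ## every selected guide passed the filters
  expect_true(all(res$design$guides$guide_id %in%
                    res$candidates$guide_id[res$candidates$pass]))
  ## library TSV round-trip contains controls
  out <- file.path(withr::local_tempdir(), "lib.tsv")
  write_library(res$design, out)
  lib <- read.delim(out)
  expect_equal(nrow(lib), res$summary$library_size)
})
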