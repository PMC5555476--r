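#' Enumerate candidate guides whose cut site lies in a coding exon
#'
#' Scans both strands of the genome for 20-mer protospacers adjacent to an
#' NGG PAM whose blunt SpCas9 cut site (between protospacer positions 17
#' and 18, 3 bp 5' of the PAM) falls inside a coding exon of the target
#' gene. The cut site is recorded as the 1-based genomic coordinate of the
#' base immediately left of the cut bond; a candidate requires both bases
#' flanking the bond to lie inside the exon.
#'
#' @param genome FASTA path, `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @param models a `GeneModelSet` or list of [gene_model()] objects.
#' @return data.frame of candidates with columns `guide_id`, `gene`, `exon`,
#'   `chrom`, `strand`, `start` (leftmost coordinate of the 23-nt
#'   protospacer+PAM window), `cut_site`, `protospacer`, `pam`, `gc`.
#' @export
enumerate_candidates <- function(genome, models) {
  genome <- as_genome_chr(genome)
  out <- list()
  for (m in models) {
    if (!m$chrom %in% names(genome)) {
      stop(sprintf("chromosome %s of gene %s not in genome", m$chrom, m$gene))
    }
    S <- genome[[m$chrom]]
    L <- nchar(S)
    if (any(m$exons$end > L)) {
      stop(sprintf("exon of gene %s extends beyond end of %s (%d > %d)",
                   m$gene, m$chrom, max(m$exons$end), L))
    }
    for (e in seq_len(nrow(m$exons))) {
      a <- m$exons$start[e]; b <- m$exons$end[e]
      num <- m$exons$number[e]
      ## forward sites: window [p, p+22], PAM at p+20..p+22, cut left base p+16
      pa <- max(1L, a - 16L); pb <- min(L - 22L, b - 17L)
      if (pa <= pb) {
        p <- pa:pb
        p <- p[substring(S, p + 21L, p + 22L) == "GG"]
        if (length(p)) {
          out[[length(out) + 1L]] <- data.frame(
            gene = m$gene, exon = num, chrom = m$chrom, strand = "+",
            start = p, cut_site = p + 16L,
            protospacer = substring(S, p, p + 19L),
            pam = substring(S, p + 20L, p + 22L),
            stringsAsFactors = FALSE)
        }
      }
      ## reverse sites: window [p, p+22], PAM at p..p+2 (CCN), cut left base p+5
      pa <- max(1L, a - 5L); pb <- min(L - 22L, b - 6L)
      if (pa <= pb) {
        p <- pa:pb
        p <- p[substring(S, p, p + 1L) == "CC"]
        if (length(p)) {
          out[[length(out) + 1L]] <- data.frame(
            gene = m$gene, exon = num, chrom = m$chrom, strand = "-",
            start = p, cut_site = p + 5L,
            protospacer = revcomp(substring(S, p + 3L, p + 22L)),
            pam = revcomp(substring(S, p, p + 2L)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    cands <- data.frame(gene = character(0), exon = integer(0),
                        chrom = character(0), strand = character(0),
                        start = integer(0), cut_site = integer(0),
                        protospacer = character(0), pam = character(0),
                        stringsAsFactors = FALSE)
  } else {
    cands <- do.call(rbind, out)
  }
  cands$gc <- gc_fraction(cands$protospacer)
  cands$guide_id <- sprintf("%s_ex%d_%s%s%d", cands$gene, cands$exon,
                            cands$chrom, cands$strand, cands$cut_site)
  rownames(cands) <- NULL
  cands[, c("guide_id", "gene", "exon", "chrom", "strand", "start",
            "cut_site", "protospacer", "pam", "gc")]
}

#' Candidate filter configuration
#'
#' @param gc_min,gc_max allowed GC fraction of the protospacer
#'   (defaults 0.40-0.75, bounds inclusive).
#' @param max_homopolymer longest allowed single-nucleotide run in the
#'   protospacer (default 3; runs of 4 or more are rejected).
#' @param forbidden_sites restriction sites rejected anywhere in the
#'   protospacer+PAM on either strand. Defaults: AgeI (ACCGGT), KpnI
#'   (GGTACC), BveI/BspMI (ACCTGC), BsmI (GAATGC), BsmBI (CGTCTC).
#' @param snp_filter reject candidates whose protospacer or PAM overlaps a
#'   supplied variant position (default TRUE).
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(gc_min = 0.40, gc_max = 0.75, max_homopolymer = 3,
                          forbidden_sites = c(AgeI = "ACCGGT",
                                              KpnI = "GGTACC",
                                              BveI = "ACCTGC",
                                              BsmI = "GAATGC",
                                              BsmBI = "CGTCTC"),
                          snp_filter = TRUE) {
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 1, max_homopolymer >= 1)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = max_homopolymer,
                 forbidden_sites = forbidden_sites,
                 snp_filter = snp_filter),
            class = "FilterConfig")
}

#' Apply sequence and variant filters to candidate guides
#'
#' Rejections are annotations, not errors: the returned data.frame carries
#' `pass` (logical) and `reject_reason` (comma-joined labels among `gc`,
#' `homopolymer`, `restriction_site`, `snp`).
#'
#' @param cands candidate data.frame from [enumerate_candidates()].
#' @param cfg a [filter_config()].
#' @param snps optional data.frame of variant positions with columns
#'   `chrom`, `pos` (1-based).
#' @return `cands` with `pass` and `reject_reason` columns added.
#' @export
apply_filters <- function(cands, cfg = filter_config(), snps = NULL) {
  stopifnot(inherits(cfg, "FilterConfig"))
  n <- nrow(cands)
  reasons <- vector("list", n)
  bad_gc <- cands$gc < cfg$gc_min | cands$gc > cfg$gc_max
  run_re <- sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}",
                    cfg$max_homopolymer + 1L, cfg$max_homopolymer + 1L,
                    cfg$max_homopolymer + 1L, cfg$max_homopolymer + 1L)
  bad_run <- grepl(run_re, cands$protospacer)
  ctx <- paste0(cands$protospacer, cands$pam)
  ctx_rc <- revcomp(ctx)
  bad_rs <- rep(FALSE, n)
  for (site in cfg$forbidden_sites) {
    bad_rs <- bad_rs | grepl(site, ctx, fixed = TRUE) |
      grepl(site, ctx_rc, fixed = TRUE)
  }
  bad_snp <- rep(FALSE, n)
  if (cfg$snp_filter && !is.null(snps) && nrow(snps)) {
    for (i in seq_len(n)) {
      bad_snp[i] <- any(snps$chrom == cands$chrom[i] &
                          snps$pos >= cands$start[i] &
                          snps$pos <= cands$start[i] + 22L)
    }
  }
  lab <- cbind(gc = bad_gc, homopolymer = bad_run,
               restriction_site = bad_rs, snp = bad_snp)
  cands$pass <- !rowSums(lab)
  cands$reject_reason <- apply(lab, 1L, function(r) {
    if (any(r)) paste(colnames(lab)[r], collapse = ",") else NA_character_
  })
  cands
}

## All genomic sites matching a protospacer within max_mismatches, with an
## exact-GG PAM, on both strands. Returns chrom/strand/start/cut/mismatches.
find_guide_hits <- function(protospacer, genome_chr, genome_dna,
                            max_mismatches = 2L) {
  pat <- Biostrings::DNAString(paste0(protospacer, "NGG"))
  pat_rc <- Biostrings::reverseComplement(pat)
  hits <- list()
  for (chrom in names(genome_dna)) {
    S <- genome_chr[[chrom]]
    m <- Biostrings::matchPattern(pat, genome_dna[[chrom]],
                                  max.mismatch = max_mismatches,
                                  fixed = "subject")
    p <- Biostrings::start(m)
    if (length(p)) {
      p <- p[p >= 1L & p + 22L <= nchar(S)]
      p <- p[substring(S, p + 21L, p + 22L) == "GG"]
      if (length(p)) {
        mm <- count_mismatches(substring(S, p, p + 19L), protospacer)
        p <- p[mm <= max_mismatches]
        mm <- mm[mm <= max_mismatches]
        if (length(p)) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, strand = "+", start = p, cut_site = p + 16L,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
    m <- Biostrings::matchPattern(pat_rc, genome_dna[[chrom]],
                                  max.mismatch = max_mismatches,
                                  fixed = "subject")
    p <- Biostrings::start(m)
    if (length(p)) {
      p <- p[p >= 1L & p + 22L <= nchar(S)]
      p <- p[substring(S, p, p + 1L) == "CC"]
      if (length(p)) {
        mm <- count_mismatches(revcomp(substring(S, p + 3L, p + 22L)),
                               protospacer)
        p2 <- p[mm <= max_mismatches]
        mm <- mm[mm <= max_mismatches]
        if (length(p2)) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, strand = "-", start = p2, cut_site = p2 + 5L,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), cut_site = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Classify candidate guides by genome-wide off-target hits
#'
#' All genomic sites with an NGG PAM (the N is free, the GG required) and at
#' most `max_mismatches` mismatches over the 20-nt protospacer are located
#' on both strands. A candidate is `excluded` if any hit's cut site lies
#' within the gene body (exons or introns) of a gene other than its target.
#' Otherwise, hits inside the target gene body are target hits (never
#' counted against the off-target budget) and hits outside every gene body
#' are intergenic off-targets: class 1 = two or more target hits and no
#' off-targets, class 2 = one target hit and no off-targets, class 3 = one
#' or two intergenic off-targets, class 4 = three intergenic off-targets;
#' more than three is `excluded`.
#'
#' @param cands candidate data.frame (typically filtered); must include
#'   `gene`, `chrom`, `protospacer` columns.
#' @param genome genome as for [enumerate_candidates()].
#' @param models gene models defining gene bodies.
#' @param max_mismatches protospacer mismatch budget (default 2).
#' @return `cands` with `offtarget_class` (`"1"`, `"2"`, `"3"`, `"4"`, or
#'   `"excluded"`), `n_target_hits`, `n_intergenic_offtargets` added.
#' @export
classify_offtargets <- function(cands, genome, models, max_mismatches = 2L) {
  genome_chr <- as_genome_chr(genome)
  genome_dna <- Biostrings::DNAStringSet(genome_chr)
  bodies <- gene_body_table(models)
  n <- nrow(cands)
  cls <- character(n)
  n_t <- integer(n)
  n_i <- integer(n)
  for (i in seq_len(n)) {
    hits <- find_guide_hits(cands$protospacer[i], genome_chr, genome_dna,
                            max_mismatches)
    if (!nrow(hits)) {
      stop(sprintf("internal consistency error: guide %s matches nowhere, not even its own site",
                   cands$protospacer[i]))
    }
    ## a hit is inside a gene body if its cut bond lies within [start, end]
    in_gene <- matrix(FALSE, nrow(hits), nrow(bodies))
    for (g in seq_len(nrow(bodies))) {
      in_gene[, g] <- hits$chrom == bodies$chrom[g] &
        hits$cut_site >= bodies$start[g] &
        hits$cut_site + 1L <= bodies$end[g]
    }
    target_col <- match(cands$gene[i], bodies$gene)
    if (is.na(target_col)) {
      hit_target <- rep(FALSE, nrow(hits))
      hit_other <- rowSums(in_gene) > 0
    } else {
      hit_target <- in_gene[, target_col]
      hit_other <- rowSums(in_gene[, -target_col, drop = FALSE]) > 0
    }
    n_t[i] <- sum(hit_target)
    n_i[i] <- sum(!hit_target & !hit_other)
    if (any(hit_other & !hit_target)) {
      cls[i] <- "excluded"
    } else if (n_i[i] == 0L) {
      cls[i] <- if (n_t[i] >= 2L) "1" else "2"
    } else if (n_i[i] <= 2L) {
      cls[i] <- "3"
    } else if (n_i[i] == 3L) {
      cls[i] <- "4"
    } else {
      cls[i] <- "excluded"
    }
  }
  cands$offtarget_class <- cls
  cands$n_target_hits <- n_t
  cands$n_intergenic_offtargets <- n_i
  cands
}

#' Rank rules combining off-target class and sequence score
#'
#' Default tiers: rank 1 = class 1 with score > 0; rank 2 = classes 1-3
#' with score > 0.85; rank 3 = classes 1-4 with score > 0.85; rank 4 =
#' classes 1-3 with score in \[0, 0.85\]; rank 5 = classes 1-4 with score
#' in \[-1, 0.85\]. Ranks are evaluated in order and a guide receives the
#' first rank it satisfies.
#'
#' @return data.frame of rules with list-column `classes` and score bounds
#'   (`score_min` exclusive when `min_open`, `score_max` inclusive).
#' @export
rank_rules <- function() {
  data.frame(rank = 1:5,
             classes = I(list(1L, 1:3, 1:4, 1:3, 1:4)),
             score_min = c(0, 0.85, 0.85, 0, -1),
             min_open = c(TRUE, TRUE, TRUE, FALSE, FALSE),
             score_max = c(Inf, Inf, Inf, 0.85, 0.85))
}

#' Assign selection ranks to classified, scored candidates
#'
#' @param cands data.frame with `offtarget_class` and `seq_score` columns.
#' @param rules rule table from [rank_rules()].
#' @return `cands` with an integer `rank` column (`NA` = unranked).
#' @export
assign_ranks <- function(cands, rules = rank_rules()) {
  if (!"seq_score" %in% colnames(cands)) stop("candidates lack seq_score")
  if (!"offtarget_class" %in% colnames(cands)) {
    stop("candidates lack offtarget_class")
  }
  cl <- suppressWarnings(as.integer(cands$offtarget_class))
  rank <- rep(NA_integer_, nrow(cands))
  for (r in seq_len(nrow(rules))) {
    lo_ok <- if (rules$min_open[r]) cands$seq_score > rules$score_min[r] else
      cands$seq_score >= rules$score_min[r]
    ok <- is.na(rank) & !is.na(cl) & cl %in% rules$classes[[r]] &
      lo_ok & cands$seq_score <= rules$score_max[r]
    rank[ok] <- rules$rank[r]
  }
  cands$rank <- rank
  cands
}

#' Greedy exon-covering guide selection
#'
#' Iterates ranks 1 to 5; within each rank, selection proceeds in rounds.
#' In every round each gene still below its quota receives at most one
#' guide: the highest-scoring unselected candidate, preferring exons that
#' have no selected guide yet and falling back to already-targeted exons
#' only when no fresh-exon candidate remains in the current rank. Ties are
#' broken by lower exon number, then lexicographic protospacer. Duplicate
#' protospacers across genes keep the first occurrence in gene order and
#' log a conflict.
#'
#' @param cands ranked candidate data.frame from [assign_ranks()].
#' @param guides_per_gene maximum guides per gene (default 4).
#' @param controls optional data.frame of control guides (e.g. targeting
#'   reporter genes) with at least `guide_id` and `protospacer` columns;
#'   appended unchanged.
#' @param gene_order gene processing order (default: order of appearance).
#' @return an object of class `LibraryDesign`: list with `guides`
#'   (selected candidates + `rank`, `round`), `controls`, `untargeted`
#'   (genes with no selected guide), `conflicts` (dropped duplicate
#'   protospacers), `library_size`.
#' @export
select_library <- function(cands, guides_per_gene = 4L, controls = NULL,
                           gene_order = unique(cands$gene)) {
  ranked <- cands[!is.na(cands$rank), , drop = FALSE]
  ## resolve duplicate protospacers across genes: first gene in order wins
  conflicts <- data.frame(protospacer = character(0), kept_gene = character(0),
                          dropped_gene = character(0), stringsAsFactors = FALSE)
  if (nrow(ranked)) {
    ranked <- ranked[order(match(ranked$gene, gene_order)), , drop = FALSE]
    first <- match(ranked$protospacer, ranked$protospacer)
    dup <- seq_len(nrow(ranked)) != first
    cross <- dup & ranked$gene != ranked$gene[first]
    if (any(cross)) {
      conflicts <- data.frame(protospacer = ranked$protospacer[cross],
                              kept_gene = ranked$gene[first][cross],
                              dropped_gene = ranked$gene[cross],
                              stringsAsFactors = FALSE)
    }
    ranked <- ranked[!dup, , drop = FALSE]
  }
  selected_idx <- integer(0)
  sel_round <- integer(0)
  n_sel <- setNames(integer(length(gene_order)), gene_order)
  used_exons <- setNames(vector("list", length(gene_order)), gene_order)
  taken <- rep(FALSE, nrow(ranked))
  for (r in sort(unique(ranked$rank))) {
    round_no <- 0L
    repeat {
      round_no <- round_no + 1L
      added <- FALSE
      for (g in gene_order) {
        if (n_sel[[g]] >= guides_per_gene) next
        pool <- which(!taken & ranked$rank == r & ranked$gene == g)
        if (!length(pool)) next
        fresh <- pool[!(ranked$exon[pool] %in% used_exons[[g]])]
        pick_from <- if (length(fresh)) fresh else pool
        ord <- order(-ranked$seq_score[pick_from], ranked$exon[pick_from],
                     ranked$protospacer[pick_from])
        pick <- pick_from[ord[1L]]
        taken[pick] <- TRUE
        selected_idx <- c(selected_idx, pick)
        sel_round <- c(sel_round, round_no)
        n_sel[[g]] <- n_sel[[g]] + 1L
        used_exons[[g]] <- c(used_exons[[g]], ranked$exon[pick])
        added <- TRUE
      }
      if (!added || all(n_sel >= guides_per_gene)) break
    }
  }
  guides <- ranked[selected_idx, , drop = FALSE]
  guides$round <- sel_round
  rownames(guides) <- NULL
  n_controls <- if (is.null(controls)) 0L else nrow(controls)
  structure(list(guides = guides,
                 controls = controls,
                 untargeted = setdiff(gene_order, guides$gene),
                 conflicts = conflicts,
                 library_size = nrow(guides) + n_controls),
            class = "LibraryDesign")
}

#' @export
print.LibraryDesign <- function(x, ...) {
  cat(sprintf("LibraryDesign: %d guides for %d genes (+%d controls, %d untargeted genes)\n",
              nrow(x$guides), length(unique(x$guides$gene)),
              if (is.null(x$controls)) 0L else nrow(x$controls),
              length(x$untargeted)))
  invisible(x)
}

#' Full library design pipeline
#'
#' Enumerates candidates, applies sequence/variant filters, classifies
#' off-targets, scores and ranks candidates, and greedily selects up to
#' `guides_per_gene` guides per gene.
#'
#' @param genome genome (FASTA path, `DNAStringSet`, or named character).
#' @param models gene models (`GeneModelSet` or path to GTF/GFF3).
#' @param table a [score_table()] for sequence scoring.
#' @param snps optional variant positions (data.frame `chrom`, `pos`, or a
#'   VCF path).
#' @param filter_cfg a [filter_config()].
#' @param rules a [rank_rules()] table.
#' @param guides_per_gene guides per gene quota (default 4).
#' @param controls optional control-guide data.frame (see
#'   [select_library()]).
#' @param max_mismatches off-target mismatch budget (default 2).
#' @return list with `design` (a `LibraryDesign`), `candidates` (the fully
#'   annotated candidate table), and `summary` (per-rank candidate/added/
#'   cumulative counts plus control and total library sizes).
#' @export
design_library <- function(genome, models, table, snps = NULL,
                           filter_cfg = filter_config(), rules = rank_rules(),
                           guides_per_gene = 4L, controls = NULL,
                           max_mismatches = 2L) {
  if (is.character(models) && length(models) == 1L) {
    models <- read_gene_models(models)
  }
  if (is.character(snps) && length(snps) == 1L) {
    snps <- read_variant_positions(snps)
  }
  cands <- enumerate_candidates(genome, models)
  cands <- apply_filters(cands, filter_cfg, snps)
  kept <- cands[cands$pass, , drop = FALSE]
  kept <- classify_offtargets(kept, genome, models, max_mismatches)
  kept$seq_score <- score_guides(kept$protospacer, table)
  kept <- assign_ranks(kept, rules)
  design <- select_library(kept, guides_per_gene, controls,
                           gene_order = vapply(models, `[[`, character(1L),
                                               "gene"))
  per_rank <- data.frame(
    rank = rules$rank,
    n_candidates = vapply(rules$rank, function(r) sum(kept$rank == r,
                                                      na.rm = TRUE), numeric(1L)),
    n_added = vapply(rules$rank, function(r)
      sum(design$guides$rank == r), numeric(1L)))
  per_rank$cumulative <- cumsum(per_rank$n_added)
  list(design = design,
       candidates = cands,
       summary = list(per_rank = per_rank,
                      n_controls = if (is.null(controls)) 0L else nrow(controls),
                      n_selected = nrow(design$guides),
                      library_size = design$library_size))
}

#' Read variant positions from a VCF
#'
#' Only CHROM and POS are used.
#'
#' @param path VCF file.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_variant_positions <- function(path) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  data.frame(chrom = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             stringsAsFactors = FALSE)
}

#' Write a designed library as TSV
#'
#' Columns: GUIDE_ID, GENE, EXON, CHROM, CUT_POS (1-based), STRAND,
#' PROTOSPACER, PAM, GC, SEQSCORE, CLASS, RANK, ROUND. Control guides are
#' appended with empty coordinate fields.
#'
#' @param design a `LibraryDesign` from [select_library()].
#' @param path output TSV path.
#' @export
write_library <- function(design, path) {
  g <- design$guides
  df <- data.frame(GUIDE_ID = g$guide_id, GENE = g$gene, EXON = g$exon,
                   CHROM = g$chrom, CUT_POS = g$cut_site, STRAND = g$strand,
                   PROTOSPACER = g$protospacer, PAM = g$pam, GC = g$gc,
                   SEQSCORE = g$seq_score, CLASS = g$offtarget_class,
                   RANK = g$rank, ROUND = g$round, stringsAsFactors = FALSE)
  if (!is.null(design$controls) && nrow(design$controls)) {
    ctrl <- design$controls
    df <- rbind(df, data.frame(
      GUIDE_ID = ctrl$guide_id,
      GENE = if ("gene" %in% colnames(ctrl)) ctrl$gene else "CONTROL",
      EXON = NA, CHROM = NA, CUT_POS = NA, STRAND = NA,
      PROTOSPACER = ctrl$protospacer, PAM = NA, GC = NA, SEQSCORE = NA,
      CLASS = NA, RANK = NA, ROUND = NA, stringsAsFactors = FALSE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
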