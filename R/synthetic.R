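#' Specification for a synthetic genome
#'
#' Describes a small genome with multi-exon genes laid out at regular
#' intervals, optional planted off-target sites for the planted on-target
#' guide of each gene, and optional common-variant positions.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total genes, distributed round-robin over chromosomes.
#' @param exons_per_gene coding exons per gene.
#' @param exon_length,intron_length exon and intron sizes (bp).
#' @param offtargets_per_gene planted near-matches of each gene's planted
#'   guide (default 0).
#' @param offtarget_mismatches protospacer mismatches of each planted
#'   off-target site (default 2).
#' @param offtarget_genic fraction of planted off-targets placed inside
#'   another gene's intron rather than intergenically (default 0).
#' @param snp_density per-bp probability of a variant site (default 0).
#' @param seed integer seed; identical specs produce byte-identical output.
#' @return a `SynthGenomeSpec` list.
#' @export
synth_genome_spec <- function(n_chromosomes = 1L, chrom_length = 10000L,
                              n_genes = 4L, exons_per_gene = 3L,
                              exon_length = 150L, intron_length = 80L,
                              offtargets_per_gene = 0L,
                              offtarget_mismatches = 2L,
                              offtarget_genic = 0,
                              snp_density = 0, seed = 1L) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 0,
            exons_per_gene >= 1, exon_length >= 30, intron_length >= 0,
            offtargets_per_gene >= 0, offtarget_mismatches >= 0,
            offtarget_genic >= 0, offtarget_genic <= 1, snp_density >= 0)
  span <- exons_per_gene * exon_length + (exons_per_gene - 1L) * intron_length
  per_chrom <- ceiling(n_genes / n_chromosomes)
  if (per_chrom * (span + 100L) + 100L > chrom_length) {
    stop("planted genes exceed chromosome length; enlarge chrom_length")
  }
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 offtargets_per_gene = as.integer(offtargets_per_gene),
                 offtarget_mismatches = as.integer(offtarget_mismatches),
                 offtarget_genic = offtarget_genic,
                 snp_density = snp_density,
                 seed = as.integer(seed),
                 gene_span = span),
            class = "SynthGenomeSpec")
}

## overwrite s[at..at+nchar(insert)-1] with insert
splice_into <- function(s, at, insert) {
  paste0(substring(s, 1L, at - 1L), insert,
         substring(s, at + nchar(insert), nchar(s)))
}

random_dna <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

mutate_protospacer <- function(seq, n_mismatches) {
  ch <- strsplit(seq, "")[[1L]]
  pos <- sample(20L, n_mismatches)
  for (p in pos) ch[p] <- sample(setdiff(NUCS, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with gene models and ground truth
#'
#' Lays out multi-exon genes on random-sequence chromosomes, plants one
#' known guide site (20-mer + CGG PAM) inside exon 1 of each gene, and
#' optionally plants mismatched copies of those guides at intergenic or
#' genic locations as known off-target sites. Optionally emits FASTA, GTF,
#' VCF, and truth-table TSV files.
#'
#' @param spec a [synth_genome_spec()].
#' @param dir optional output directory; when given, `genome.fa`,
#'   `models.gtf`, `variants.vcf`, `truth_on_targets.tsv`, and
#'   `truth_offtargets.tsv` are written there.
#' @return list with `genome` (named character), `models`
#'   (`GeneModelSet`), `variants` (data.frame chrom/pos/ref/alt), `truth`
#'   (list of `on_targets` and `offtargets` data.frames), and `paths`
#'   (when `dir` was given).
#' @export
make_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SynthGenomeSpec"))
  withr::with_seed(spec$seed, {
    chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    genome <- setNames(vapply(chroms, function(x)
      random_dna(spec$chrom_length), character(1L)), chroms)
    models <- list()
    on_targets <- list()
    used <- lapply(chroms, function(x) integer(0))  # occupied window starts
    names(used) <- chroms

    if (spec$n_genes > 0L) {
      gene_chrom <- chroms[((seq_len(spec$n_genes) - 1L) %%
                              spec$n_chromosomes) + 1L]
      for (ci in seq_along(chroms)) {
        idx <- which(gene_chrom == chroms[ci])
        n <- length(idx)
        if (!n) next
        gap <- (spec$chrom_length - n * spec$gene_span) %/% (n + 1L)
        for (j in seq_len(n)) {
          gi <- idx[j]
          gname <- sprintf("G%03d", gi)
          gstart <- gap + (j - 1L) * (spec$gene_span + gap) + 1L
          ex_start <- gstart + (seq_len(spec$exons_per_gene) - 1L) *
            (spec$exon_length + spec$intron_length)
          exons <- data.frame(start = ex_start,
                              end = ex_start + spec$exon_length - 1L)
          strand <- if (gi %% 2L == 1L) "+" else "-"
          models[[gname]] <- gene_model(gname, chroms[ci], strand, exons)
          ## plant a forward-strand guide site fully inside exon 1
          site_at <- exons$start[1L] + 5L
          proto <- random_dna(20L)
          genome[[chroms[ci]]] <- splice_into(genome[[chroms[ci]]], site_at,
                                              paste0(proto, "CGG"))
          used[[chroms[ci]]] <- c(used[[chroms[ci]]], site_at)
          on_targets[[gname]] <- data.frame(
            gene = gname, chrom = chroms[ci], strand = "+",
            start = site_at, cut_site = site_at + 16L,
            protospacer = proto, pam = "CGG", stringsAsFactors = FALSE)
        }
      }
    }
    models <- structure(models, class = "GeneModelSet")
    bodies <- if (length(models)) gene_body_table(models) else NULL

    offtargets <- list()
    if (spec$offtargets_per_gene > 0L && length(models)) {
      for (gname in names(models)) {
        proto <- on_targets[[gname]]$protospacer
        for (k in seq_len(spec$offtargets_per_gene)) {
          genic <- stats::runif(1L) < spec$offtarget_genic
          variant <- mutate_protospacer(proto, spec$offtarget_mismatches)
          placed <- FALSE
          for (try in 1:200) {
            if (genic) {
              others <- setdiff(names(models), gname)
              others <- others[vapply(others, function(g)
                spec$intron_length >= 30L && nrow(models[[g]]$exons) > 1L,
                logical(1L))]
              if (!length(others)) { genic <- FALSE; next }
              host <- models[[sample(others, 1L)]]
              iv <- sample(nrow(host$exons) - 1L, 1L)
              ## anywhere in the intron that keeps the 23-mer inside it
              lo <- host$exons$end[iv] + 2L
              hi <- host$exons$start[iv + 1L] - 25L
              if (hi < lo) next
              at <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
              chrom <- host$chrom
            } else {
              chrom <- sample(names(genome), 1L)
              at <- sample(spec$chrom_length - 30L, 1L) + 3L
              ## reject positions inside or near any gene body or used site
              if (!is.null(bodies)) {
                bc <- bodies[bodies$chrom == chrom, , drop = FALSE]
                if (nrow(bc) && any(at + 25L >= bc$start - 30L &
                                    at <= bc$end + 30L)) next
              }
            }
            if (any(abs(used[[chrom]] - at) < 25L)) next
            genome[[chrom]] <- splice_into(genome[[chrom]], at,
                                           paste0(variant, "TGG"))
            used[[chrom]] <- c(used[[chrom]], at)
            offtargets[[length(offtargets) + 1L]] <- data.frame(
              gene = gname, chrom = chrom, strand = "+", start = at,
              cut_site = at + 16L, protospacer_variant = variant,
              mismatches = spec$offtarget_mismatches, genic = genic,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed) stop("could not place planted off-target site")
        }
      }
    }

    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           stringsAsFactors = FALSE)
    if (spec$snp_density > 0) {
      for (chrom in names(genome)) {
        pos <- which(stats::runif(spec$chrom_length) < spec$snp_density)
        if (length(pos)) {
          ref <- substring(genome[[chrom]], pos, pos)
          alt <- vapply(ref, function(r) sample(setdiff(NUCS, r), 1L),
                        character(1L), USE.NAMES = FALSE)
          variants <- rbind(variants, data.frame(
            chrom = chrom, pos = pos, ref = ref, alt = alt,
            stringsAsFactors = FALSE))
        }
      }
    }

    truth <- list(
      on_targets = if (length(on_targets)) do.call(rbind, c(on_targets,
                                                            make.row.names = FALSE))
      else data.frame(),
      offtargets = if (length(offtargets)) do.call(rbind, c(offtargets,
                                                            make.row.names = FALSE))
      else data.frame())

    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(fasta = file.path(dir, "genome.fa"),
                    gtf = file.path(dir, "models.gtf"),
                    vcf = file.path(dir, "variants.vcf"),
                    on_targets = file.path(dir, "truth_on_targets.tsv"),
                    offtargets = file.path(dir, "truth_offtargets.tsv"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                  paths$fasta)
      write_gene_models(models, paths$gtf)
      write_variants_vcf(variants, paths$vcf)
      write.table(truth$on_targets, paths$on_targets, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(truth$offtargets, paths$offtargets, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(genome = genome, models = models, variants = variants,
         truth = truth, paths = paths)
  })
}

#' Write variant positions as a minimal VCF
#'
#' @param variants data.frame with columns chrom, pos, ref, alt.
#' @param path output path (plain-text VCFv4.2).
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$chrom, variants$pos,
            variants$ref, variants$alt)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Specification for a synthetic dropout screen
#'
#' Emulates a pooled knockout screen: T0 counts are negative-binomially
#' distributed around uniform library representation; guides targeting
#' essential genes drop out at the endpoint by `2^(-effect_size *
#' efficiency)`, where efficiency is either 1 or, when a planted score
#' table is supplied, a logistic function of the guide's sequence score.
#'
#' @param n_genes number of target genes (ignored when a library is given
#'   to [make_screen()]).
#' @param essential_fraction fraction of genes that are essential
#'   (default 0.1, matching the prior expectation for human cell lines).
#' @param guides_per_gene guides per gene in the generated library.
#' @param replicates endpoint replicates.
#' @param depth expected sequencing depth per sample (reads).
#' @param effect_size log2 dropout of a fully efficient guide against an
#'   essential gene (default 3).
#' @param dispersion negative binomial size parameter `r`
#'   (variance = mu + mu^2/r; default 10).
#' @param score_table optional planted [score_table()] driving guide
#'   efficiency.
#' @param efficiency_slope,efficiency_intercept logistic efficiency model
#'   `plogis(slope * score + intercept)` (defaults 1.5 and 0, spanning
#'   efficiencies ~0.01-0.99 over scores -4..4).
#' @param n_nontargeting nontargeting control guides (gene label
#'   `"NONTARGETING"`, no dropout; default 0).
#' @param seed integer seed.
#' @return a `SynthScreenSpec` list.
#' @export
synth_screen_spec <- function(n_genes = 100L, essential_fraction = 0.1,
                              guides_per_gene = 4L, replicates = 3L,
                              depth = 1e7, effect_size = 3,
                              dispersion = 10, score_table = NULL,
                              efficiency_slope = 1.5,
                              efficiency_intercept = 0,
                              n_nontargeting = 0L, seed = 1L) {
  stopifnot(essential_fraction > 0, essential_fraction < 1, depth > 0,
            guides_per_gene >= 1, replicates >= 1, dispersion > 0,
            effect_size >= 0, n_nontargeting >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 essential_fraction = essential_fraction,
                 guides_per_gene = as.integer(guides_per_gene),
                 replicates = as.integer(replicates),
                 depth = depth, effect_size = effect_size,
                 dispersion = dispersion, score_table = score_table,
                 efficiency_slope = efficiency_slope,
                 efficiency_intercept = efficiency_intercept,
                 n_nontargeting = as.integer(n_nontargeting),
                 seed = as.integer(seed)),
            class = "SynthScreenSpec")
}

#' Simulate a pooled dropout screen with known ground truth
#'
#' @param spec a [synth_screen_spec()].
#' @param library optional data.frame with columns `guide_id`, `gene`,
#'   `sequence` (20-mers); generated randomly from the spec when absent.
#' @param essential_genes optional fixed set of essential genes; by default
#'   a fraction `essential_fraction` of the genes is sampled. Supplying the
#'   set lets several simulated screens of the same library share one
#'   ground truth, as in a real cell-line panel.
#' @return list with `rc` (a [readcount_matrix()] with one T0 control and
#'   `replicates` endpoint samples) and `truth` (list: `essential_genes`,
#'   named `guide_efficiency`, named `guide_score`, `library`).
#' @export
make_screen <- function(spec, library = NULL, essential_genes = NULL) {
  stopifnot(inherits(spec, "SynthScreenSpec"))
  withr::with_seed(spec$seed, {
    if (is.null(library)) {
      genes <- sprintf("G%04d", seq_len(spec$n_genes))
      library <- data.frame(
        guide_id = paste0(rep(genes, each = spec$guides_per_gene), "_g",
                          rep(seq_len(spec$guides_per_gene),
                              times = spec$n_genes)),
        gene = rep(genes, each = spec$guides_per_gene),
        sequence = vapply(seq_len(spec$n_genes * spec$guides_per_gene),
                          function(i) random_dna(20L), character(1L)),
        stringsAsFactors = FALSE)
    }
    genes <- unique(library$gene)
    if (spec$n_nontargeting > 0L) {
      library <- rbind(library, data.frame(
        guide_id = sprintf("NT_%04d", seq_len(spec$n_nontargeting)),
        gene = "NONTARGETING",
        sequence = vapply(seq_len(spec$n_nontargeting),
                          function(i) random_dna(20L), character(1L)),
        stringsAsFactors = FALSE))
    }
    if (is.null(essential_genes)) {
      n_ess <- max(1L, round(spec$essential_fraction * length(genes)))
      essential <- sample(genes, n_ess)
    } else {
      essential <- intersect(genes, essential_genes)
    }

    scores <- if (!is.null(spec$score_table)) {
      score_guides(library$sequence, spec$score_table)
    } else rep(NA_real_, nrow(library))
    eff <- if (!is.null(spec$score_table)) {
      stats::plogis(spec$efficiency_slope * scores +
                      spec$efficiency_intercept)
    } else rep(1, nrow(library))
    is_ess_guide <- library$gene %in% essential
    eff[!is_ess_guide] <- 0  # efficiency only matters where there is dropout

    ng <- nrow(library)
    mu0 <- spec$depth / ng
    t0 <- rnbinom(ng, mu = mu0, size = spec$dispersion)
    a <- ifelse(is_ess_guide,
                2^(-spec$effect_size * ifelse(is_ess_guide, eff, 0)), 1)
    mu_end <- spec$depth * a / sum(a)
    counts <- cbind(T0 = t0,
                    vapply(seq_len(spec$replicates), function(r)
                      rnbinom(ng, mu = mu_end, size = spec$dispersion),
                      numeric(ng)))
    colnames(counts) <- c("T0", sprintf("END_R%d", seq_len(spec$replicates)))
    rownames(counts) <- library$guide_id
    roles <- setNames(c("t0_control", rep("endpoint", spec$replicates)),
                      colnames(counts))
    rc <- readcount_matrix(counts, setNames(library$gene, library$guide_id),
                           roles)
    list(rc = rc,
         truth = list(essential_genes = sort(essential),
                      guide_efficiency = setNames(eff, library$guide_id),
                      guide_score = setNames(scores, library$guide_id),
                      library = library))
  })
}

#' Exhaustive off-target oracle
#'
#' Brute-force scan of every offset on both strands of a small genome for
#' sites with an exact-GG NGG PAM and at most `max_mismatches` protospacer
#' mismatches. Independent of the pattern-matching machinery used by
#' [classify_offtargets()]; intended as a verification oracle for genomes
#' up to ~1 Mb.
#'
#' @param protospacer a 20-mer.
#' @param genome genome as for [enumerate_candidates()].
#' @param max_mismatches mismatch budget (default 2).
#' @return data.frame with `chrom`, `strand`, `start` (leftmost coordinate
#'   of the 23-nt window), `cut_site`, `mismatches`.
#' @export
oracle_offtargets <- function(protospacer, genome, max_mismatches = 2L) {
  check_guide_alphabet(protospacer, "protospacer")
  genome <- as_genome_chr(genome)
  if (sum(nchar(genome)) > 1e6) stop("oracle is exhaustive; genome must be <=1 Mb")
  hits <- list()
  for (chrom in names(genome)) {
    S <- genome[[chrom]]
    L <- nchar(S)
    if (L < 23L) next
    p <- 1:(L - 22L)
    fwd <- p[substring(S, p + 21L, p + 22L) == "GG"]
    if (length(fwd)) {
      mm <- count_mismatches(substring(S, fwd, fwd + 19L), protospacer)
      keep <- mm <= max_mismatches
      if (any(keep)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = "+", start = fwd[keep],
          cut_site = fwd[keep] + 16L, mismatches = mm[keep],
          stringsAsFactors = FALSE)
      }
    }
    rev <- p[substring(S, p, p + 1L) == "CC"]
    if (length(rev)) {
      mm <- count_mismatches(revcomp(substring(S, rev + 3L, rev + 22L)),
                             protospacer)
      keep <- mm <= max_mismatches
      if (any(keep)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, strand = "-", start = rev[keep],
          cut_site = rev[keep] + 5L, mismatches = mm[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), cut_site = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}
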