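#' Positional nucleotide score table for 20-mer guides
#'
#' An 4 x 20 weight matrix (rows A, C, G, T; columns positions 1-20, where
#' position 1 is the PAM-distal end and position 20 the PAM-proximal base).
#' A guide's sequence score is the sum of the weights at its 20 positions.
#'
#' @param weights numeric 4 x 20 matrix with rownames A, C, G, T and
#'   colnames P1..P20.
#' @param provenance character vector describing the contributing samples.
#' @param scale_anchor length-2 character/numeric vector `(nucleotide,
#'   position)` of the most extreme cell used for scaling.
#' @return an object of class `ScoreTable`.
#' @export
score_table <- function(weights, provenance = character(0),
                        scale_anchor = NULL) {
  weights <- as.matrix(weights)
  if (!identical(dim(weights), c(4L, 20L))) {
    stop("score table must be 4 nucleotides x 20 positions")
  }
  if (is.null(rownames(weights))) rownames(weights) <- NUCS
  if (!identical(rownames(weights), NUCS)) {
    weights <- weights[NUCS, , drop = FALSE]
  }
  colnames(weights) <- paste0("P", 1:20)
  structure(list(weights = weights, provenance = provenance,
                 scale_anchor = scale_anchor),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat("ScoreTable (4 nucleotides x 20 positions)\n")
  if (!is.null(x$scale_anchor)) {
    cat(sprintf("  scale anchor: %s%s\n", x$scale_anchor[1L], x$scale_anchor[2L]))
  }
  print(round(x$weights, 3))
  invisible(x)
}

## counts of each nucleotide at each of the 20 positions over a pool of guides
nt_position_counts <- function(seqs) {
  m <- guide_char_matrix(seqs)
  counts <- matrix(0L, nrow = 4L, ncol = 20L, dimnames = list(NUCS, NULL))
  for (pos in 1:20) {
    counts[, pos] <- tabulate(factor(m[pos, ], levels = NUCS), nbins = 4L)
  }
  counts
}

#' Derive the positional delta-frequency score table from screen data
#'
#' For each endpoint sample (each replicate column of each supplied
#' fold-change matrix), genes in `core_genes` with exactly six retained
#' guides are split into the three best (most negative fold-change) and
#' three worst guides; ties are broken by lexicographic guide sequence. The
#' per-position nucleotide frequencies of the pooled worst guides are
#' subtracted from those of the pooled best guides, the per-sample tables
#' are summed, and the sum is scaled so the most extreme absolute cell
#' equals one. Cells never observed in either pool across all samples (for
#' example when the source library excludes a nucleotide at the PAM-proximal
#' positions) are assigned a score of -1.
#'
#' @param fc_samples a [foldchange_matrix()] or a list of them; every
#'   replicate column is treated as one sample.
#' @param guide_seqs named character vector mapping guide ids to 20-mer
#'   sequences; if `NULL`, guide ids are assumed to be the sequences.
#' @param core_genes character vector of reference essential genes used to
#'   anchor the best/worst split.
#' @return a [score_table()].
#' @export
derive_score_table <- function(fc_samples, guide_seqs = NULL, core_genes) {
  if (inherits(fc_samples, "FoldchangeMatrix")) fc_samples <- list(fc_samples)
  stopifnot(all(vapply(fc_samples, inherits, logical(1L), "FoldchangeMatrix")))
  delta_sum <- matrix(0, 4L, 20L, dimnames = list(NUCS, NULL))
  obs <- matrix(0L, 4L, 20L, dimnames = list(NUCS, NULL))
  n_samples_used <- 0L
  provenance <- character(0)

  for (fcm in fc_samples) {
    seqs_of <- if (is.null(guide_seqs)) {
      setNames(rownames(fcm$fc), rownames(fcm$fc))
    } else guide_seqs
    for (j in seq_len(ncol(fcm$fc))) {
      v <- fcm$fc[, j]
      retained <- names(v)[is.finite(v)]
      genes <- unname(fcm$gene[retained])
      cnt <- table(genes)
      qual <- intersect(core_genes, names(cnt)[cnt == 6L])
      if (!length(qual)) next
      best <- character(0); worst <- character(0)
      for (g in qual) {
        ids <- retained[genes == g]
        sq <- unname(seqs_of[ids])
        ord <- order(v[ids], sq)   # ascending fc; ties by sequence
        best <- c(best, sq[ord[1:3]])
        worst <- c(worst, sq[ord[4:6]])
      }
      check_guide_alphabet(c(best, worst))
      cb <- nt_position_counts(best)
      cw <- nt_position_counts(worst)
      delta_sum <- delta_sum + cb / length(best) - cw / length(worst)
      obs <- obs + cb + cw
      n_samples_used <- n_samples_used + 1L
      provenance <- c(provenance,
                      sprintf("sample %s (%d genes)", colnames(fcm$fc)[j],
                              length(qual)))
    }
  }
  if (n_samples_used == 0L) stop("no qualifying gene in any sample")
  extreme <- max(abs(delta_sum))
  if (extreme < 1e-12) stop("all-zero table: best and worst pools are identical")
  anchor_idx <- which(abs(delta_sum) == extreme, arr.ind = TRUE)[1L, ]
  w <- delta_sum / extreme
  w[obs == 0L] <- -1
  score_table(w, provenance = provenance,
              scale_anchor = c(NUCS[anchor_idx[1L]],
                               as.character(anchor_idx[2L])))
}

#' Score 20-mer guide sequences against a score table
#'
#' The score is the sum over the 20 positions of the table weight for the
#' nucleotide the guide carries at that position.
#'
#' @param seqs character vector of 20-mer A/C/G/T sequences.
#' @param table a [score_table()].
#' @return numeric vector of scores, one per sequence.
#' @export
score_guides <- function(seqs, table) {
  stopifnot(inherits(table, "ScoreTable"))
  if (!length(seqs)) return(numeric(0))
  check_guide_alphabet(seqs)
  m <- guide_char_matrix(seqs)
  idx <- match(m, NUCS)
  w <- table$weights[cbind(idx, rep(1:20, times = length(seqs)))]
  colSums(matrix(w, nrow = 20L))
}

#' @rdname score_guides
#' @param seq a single 20-mer sequence.
#' @export
score_guide <- function(seq, table) score_guides(seq, table)[1L]

#' Validate a score table against held-out screen data
#'
#' Among guides targeting reference essential genes, guides in the top
#' quartile of sequence scores are compared with guides in the bottom
#' quartile by a two-sided Welch (unequal-variance) t-test on their
#' replicate-averaged fold-changes.
#'
#' @param fc a [foldchange_matrix()] from a held-out screen.
#' @param guide_seqs named guide-to-sequence map (`NULL` = ids are sequences).
#' @param table a [score_table()].
#' @param refs a [reference_sets()]; at least 8 retained guides must target
#'   reference essentials.
#' @return list with `top_fc`, `bottom_fc` (fold-change samples), `p_value`
#'   (NA with `degenerate = TRUE` when the test is undefined, e.g. zero
#'   variance in both quartiles), and the two quartile means.
#' @export
quartile_validation <- function(fc, guide_seqs = NULL, table, refs) {
  stopifnot(inherits(fc, "FoldchangeMatrix"), inherits(refs, "ReferenceSets"))
  mfc <- rowMeans(fc$fc, na.rm = TRUE)
  ess <- names(mfc)[fc$gene %in% refs$essentials & is.finite(mfc)]
  if (length(ess) < 8L) {
    stop(sprintf("need >=8 guides targeting reference essentials (have %d)",
                 length(ess)))
  }
  seqs <- if (is.null(guide_seqs)) ess else unname(guide_seqs[ess])
  scores <- score_guides(seqs, table)
  q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
  top <- mfc[ess][scores >= q[2L]]
  bottom <- mfc[ess][scores <= q[1L]]
  if (!length(top) || !length(bottom)) stop("empty score quartile")
  tt <- tryCatch(t.test(top, bottom, var.equal = FALSE),
                 error = function(e) NULL)
  list(top_fc = unname(top), bottom_fc = unname(bottom),
       mean_top = mean(top), mean_bottom = mean(bottom),
       p_value = if (is.null(tt)) NA_real_ else tt$p.value,
       degenerate = is.null(tt))
}

#' Write / read a score table TSV with JSON sidecar
#'
#' The TSV has rows A, C, G, T and columns P1..P20; provenance and the
#' scale anchor go to a `.json` sidecar.
#'
#' @param table a [score_table()].
#' @param path output TSV path.
#' @return invisibly, the sidecar path.
#' @export
write_score_table <- function(table, path) {
  df <- data.frame(NT = rownames(table$weights), table$weights,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(list(provenance = table$provenance,
                            scale_anchor = table$scale_anchor),
                       sidecar, auto_unbox = FALSE, pretty = TRUE)
  invisible(sidecar)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  w <- as.matrix(df[, -1L, drop = FALSE])
  rownames(w) <- df[[1L]]
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  score_table(w,
              provenance = unlist(meta$provenance),
              scale_anchor = unlist(meta$scale_anchor))
}
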