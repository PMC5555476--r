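#' Gene model with numbered coding exons
#'
#' @param gene gene id/symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates of coding exons, non-overlapping). Exons are
#'   numbered ascending from the transcription start site, i.e. by
#'   increasing start on the plus strand and decreasing start on the minus
#'   strand.
#' @param body optional length-2 numeric `(start, end)` of the gene body
#'   (exons plus introns); defaults to the range of the exons.
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene, chrom, strand, exons, body = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons$end >= exons$start))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop(sprintf("overlapping coding exons in gene %s", gene))
  }
  exons$number <- if (strand == "+") seq_len(nrow(exons)) else
    rev(seq_len(nrow(exons)))
  if (is.null(body)) body <- c(min(exons$start), max(exons$end))
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 exons = exons, body = body),
            class = "GeneModel")
}

#' Read gene models from a GTF/GFF3 file
#'
#' Coding exons are taken from CDS features. One canonical transcript per
#' gene (the one with the longest total CDS, ties broken by transcript id)
#' defines the exon numbering; the gene body spans all features annotated
#' for the gene.
#'
#' @param path GTF or GFF3 file with CDS features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return named list of [gene_model()] objects (class `GeneModelSet`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop(sprintf("gene model file not found: %s", path))
  gr <- rtracklayer::import(path)
  if (!"type" %in% colnames(S4Vectors::mcols(gr))) {
    stop("gene model file lacks feature types")
  }
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in gene model file")
  df <- data.frame(gene = as.character(cds$gene_id),
                   tx = as.character(cds$transcript_id),
                   chrom = as.character(GenomicRanges::seqnames(cds)),
                   strand = as.character(GenomicRanges::strand(cds)),
                   start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds),
                   stringsAsFactors = FALSE)
  all_df <- data.frame(gene = as.character(gr$gene_id),
                       start = GenomicRanges::start(gr),
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
  models <- lapply(split(df, df$gene), function(g) {
    tx_len <- vapply(split(g$end - g$start + 1L, g$tx), sum, numeric(1L))
    best_tx <- names(tx_len)[order(-tx_len, names(tx_len))][1L]
    gg <- g[g$tx == best_tx, , drop = FALSE]
    span <- all_df[all_df$gene == g$gene[1L], , drop = FALSE]
    gene_model(g$gene[1L], gg$chrom[1L], gg$strand[1L],
               gg[, c("start", "end")],
               body = c(min(span$start, na.rm = TRUE),
                        max(span$end, na.rm = TRUE)))
  })
  structure(models, class = "GeneModelSet")
}

#' Write gene models as GTF
#'
#' Emits transcript and CDS lines for the canonical transcript of each
#' model, suitable for round-tripping through [read_gene_models()].
#'
#' @param models a `GeneModelSet` or list of [gene_model()] objects.
#' @param path output GTF path.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    tx <- paste0(m$gene, ".t1")
    attr_of <- function() sprintf('gene_id "%s"; transcript_id "%s";', m$gene, tx)
    c(sprintf("%s\tguidescreen\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, m$body[1L], m$body[2L], m$strand, attr_of()),
      sprintf("%s\tguidescreen\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              m$chrom, m$exons$start, m$exons$end, m$strand, attr_of()))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

## gene body table used by the off-target classifier
gene_body_table <- function(models) {
  data.frame(gene = vapply(models, `[[`, character(1L), "gene"),
             chrom = vapply(models, `[[`, character(1L), "chrom"),
             start = vapply(models, function(m) m$body[1L], numeric(1L)),
             end = vapply(models, function(m) m$body[2L], numeric(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}
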