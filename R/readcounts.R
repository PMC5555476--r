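#' Readcount matrix for a pooled CRISPR screen
#'
#' Container for integer guide-by-sample readcounts together with the
#' guide-to-gene map and sample role annotation. Exactly one sample must be
#' designated as the screen control (the T0 genomic-DNA sample collected
#' shortly after infection, or the library plasmid pool); all remaining
#' samples are endpoint measurements.
#'
#' @param counts integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample labels). Counts must be
#'   non-negative integers.
#' @param gene character vector, one gene symbol (or control class such as
#'   `"NONTARGETING"`) per guide, named by guide id or parallel to the rows
#'   of `counts`. Gene symbols are case-sensitive exact strings.
#' @param sample_roles named character vector mapping each sample label to a
#'   role: `"t0_control"`, `"plasmid_control"`, or `"endpoint"`.
#' @return an object of class `ReadcountMatrix`: a list with elements
#'   `counts`, `gene` (named by guide), `samples` (data.frame of sample,
#'   role), and `control` (the control sample label).
#' @export
readcount_matrix <- function(counts, gene, sample_roles) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have guide rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop(sprintf("duplicate guide id(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(names(gene))) names(gene) <- rownames(counts)
  if (!setequal(names(gene), rownames(counts))) {
    stop("gene map must cover exactly the guides in counts")
  }
  gene <- gene[rownames(counts)]

  roles <- c("t0_control", "plasmid_control", "endpoint")
  if (is.null(names(sample_roles)) ||
      !setequal(names(sample_roles), colnames(counts))) {
    stop("sample_roles must be named by the sample columns of counts")
  }
  bad <- setdiff(unique(sample_roles), roles)
  if (length(bad)) {
    stop(sprintf("unknown sample role(s): %s (expected %s)",
                 paste(bad, collapse = ", "), paste(roles, collapse = ", ")))
  }
  sample_roles <- sample_roles[colnames(counts)]
  ctrl <- names(sample_roles)[sample_roles != "endpoint"]
  if (length(ctrl) != 1L) {
    stop(sprintf("exactly one control sample must be designated (got %d)",
                 length(ctrl)))
  }
  structure(list(
    counts = counts,
    gene = gene,
    samples = data.frame(sample = colnames(counts),
                         role = unname(sample_roles),
                         stringsAsFactors = FALSE),
    control = ctrl
  ), class = "ReadcountMatrix")
}

#' @export
print.ReadcountMatrix <- function(x, ...) {
  cat(sprintf("ReadcountMatrix: %d guides x %d samples (control: %s)\n",
              nrow(x$counts), ncol(x$counts), x$control))
  cat(sprintf("  genes: %d\n", length(unique(x$gene))))
  invisible(x)
}

#' Read a guide readcount TSV
#'
#' Expects a tab-delimited file with a mandatory header whose first two
#' columns are the guide id and target gene, followed by one integer count
#' column per sample.
#'
#' @param path path to the TSV file.
#' @param sample_roles named character vector mapping sample column names to
#'   roles (see [readcount_matrix()]).
#' @return a [readcount_matrix()] object.
#' @export
read_readcounts <- function(path, sample_roles) {
  if (!file.exists(path)) stop(sprintf("readcount file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 3L) stop("readcount TSV needs guide, gene, and >=1 sample column")
  guide <- df[[1L]]
  gene <- setNames(df[[2L]], guide)
  cn <- colnames(df)[-(1:2)]
  counts <- matrix(NA_integer_, nrow = nrow(df), ncol = length(cn),
                   dimnames = list(guide, cn))
  for (j in seq_along(cn)) {
    v <- df[[j + 2L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) | num != floor(num) | num < 0
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-integer count '%s' at row %d (guide %s), column %s",
                   v[i], i, guide[i], cn[j]))
    }
    counts[, j] <- as.integer(num)
  }
  if (anyDuplicated(guide)) {
    dup <- unique(guide[duplicated(guide)])
    stop(sprintf("duplicate guide id(s): %s", paste(dup, collapse = ", ")))
  }
  readcount_matrix(counts, gene, sample_roles)
}

#' Normalization parameters for fold-change computation
#'
#' @param target_depth reads each sample is scaled to (default 10 million).
#' @param pseudocount reads added to every raw count before scaling
#'   (default 0.5), guaranteeing finite log fold-changes.
#' @param min_control_reads guides with fewer raw reads than this in the
#'   control sample are excluded from fold-change calculation (default 30).
#' @return a `NormalizationParams` list.
#' @export
norm_params <- function(target_depth = 1e7, pseudocount = 0.5,
                        min_control_reads = 30) {
  stopifnot(target_depth > 0, pseudocount > 0, min_control_reads >= 0)
  structure(list(target_depth = target_depth, pseudocount = pseudocount,
                 min_control_reads = min_control_reads),
            class = "NormalizationParams")
}

#' Construct a fold-change matrix directly
#'
#' Mostly useful for building small objects in examples and downstream
#' analyses that start from published fold-changes rather than readcounts.
#'
#' @param fc numeric matrix of log2 fold-changes, guides in rows (rownames =
#'   guide ids), one column per endpoint replicate.
#' @param gene character vector of gene symbols, named by guide or parallel
#'   to the rows.
#' @param mask optional data.frame of excluded guides
#'   (columns guide, gene, reason, control_reads).
#' @param params the [norm_params()] used, if any.
#' @return an object of class `FoldchangeMatrix`.
#' @export
foldchange_matrix <- function(fc, gene, mask = NULL, params = NULL) {
  if (is.data.frame(fc)) fc <- as.matrix(fc)
  if (is.null(rownames(fc))) stop("fc must have guide rownames")
  if (is.null(colnames(fc))) colnames(fc) <- paste0("R", seq_len(ncol(fc)))
  if (is.null(names(gene))) names(gene) <- rownames(fc)
  gene <- gene[rownames(fc)]
  if (anyNA(names(gene))) stop("gene map must cover all guides in fc")
  if (is.null(mask)) {
    mask <- data.frame(guide = character(0), gene = character(0),
                       reason = character(0), control_reads = numeric(0),
                       stringsAsFactors = FALSE)
  }
  structure(list(fc = fc, gene = gene, replicates = colnames(fc),
                 mask = mask, params = params),
            class = "FoldchangeMatrix")
}

#' @export
print.FoldchangeMatrix <- function(x, ...) {
  cat(sprintf("FoldchangeMatrix: %d retained guides x %d replicates (%d masked)\n",
              nrow(x$fc), ncol(x$fc), nrow(x$mask)))
  invisible(x)
}

#' Guide-level log2 fold-changes from readcounts
#'
#' Adds a pseudocount to every raw count, scales each sample so its
#' pseudocounted counts sum to `target_depth`, and computes
#' `log2(endpoint / control)` per guide for every endpoint sample. Guides
#' whose raw control (T0 or plasmid) count is below `min_control_reads` are
#' masked: they are excluded from the fold-change matrix for all replicates
#' and listed in the `mask` element with a reason. Depth scaling uses the
#' total pseudocounted reads of each sample over the full library, masked
#' guides included.
#'
#' @param rc a [readcount_matrix()].
#' @param params a [norm_params()] object.
#' @return a [foldchange_matrix()] with one column per endpoint sample.
#' @export
compute_foldchange <- function(rc, params = norm_params()) {
  stopifnot(inherits(rc, "ReadcountMatrix"),
            inherits(params, "NormalizationParams"))
  endpoints <- rc$samples$sample[rc$samples$role == "endpoint"]
  if (!length(endpoints)) stop("no endpoint samples present")
  pc <- rc$counts + params$pseudocount
  norm <- sweep(pc, 2L, colSums(pc), "/") * params$target_depth
  ctrl_raw <- rc$counts[, rc$control]
  keep <- ctrl_raw >= params$min_control_reads
  if (!any(keep)) stop("no guides pass control-read filter")
  fc <- log2(norm[keep, endpoints, drop = FALSE] / norm[keep, rc$control])
  colnames(fc) <- endpoints
  mask <- data.frame(
    guide = rownames(rc$counts)[!keep],
    gene = unname(rc$gene[!keep]),
    reason = rep(sprintf("control_reads<%g", params$min_control_reads),
                 sum(!keep)),
    control_reads = unname(ctrl_raw[!keep]),
    stringsAsFactors = FALSE
  )
  foldchange_matrix(fc, rc$gene[keep], mask = mask, params = params)
}

#' Write fold-changes and the excluded-guide sidecar
#'
#' Emits a TSV with columns GUIDE, GENE, then one column per endpoint
#' replicate; masked guides are omitted and written, with reasons, to
#' `<out>.excluded.tsv`.
#'
#' @param fc a [foldchange_matrix()].
#' @param path output TSV path.
#' @return invisibly, the sidecar path.
#' @export
write_foldchange <- function(fc, path) {
  df <- data.frame(GUIDE = rownames(fc$fc), GENE = unname(fc$gene),
                   fc$fc, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".excluded.tsv")
  write.table(fc$mask, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sidecar)
}

#' Read a fold-change TSV written by [write_foldchange()]
#'
#' @param path TSV with columns GUIDE, GENE, then replicate columns.
#' @return a [foldchange_matrix()].
#' @export
read_foldchange <- function(path) {
  if (!file.exists(path)) stop(sprintf("fold-change file not found: %s", path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  fc <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(fc) <- df[[1L]]
  foldchange_matrix(fc, setNames(df[[2L]], df[[1L]]))
}
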