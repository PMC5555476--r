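#' @importFrom stats dnorm quantile rnbinom sd setNames t.test
#' @importFrom utils read.delim write.table head packageVersion
NULL

NUCS <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming distance between each string in `seqs` and a single equal-length
## `query`. Used at small scale (off-target scans of desk-size genomes).
count_mismatches <- function(seqs, query) {
  q <- utf8ToInt(query)
  vapply(seqs, function(s) sum(utf8ToInt(s) != q), integer(1L),
         USE.NAMES = FALSE)
}

## Fraction of G/C characters per sequence.
gc_fraction <- function(x) {
  (nchar(x) - nchar(gsub("[GC]", "", x))) / nchar(x)
}

## Coerce a genome given as a file path, DNAStringSet, or named character
## vector to a named character vector of chromosome sequences.
as_genome_chr <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    stop("genome must be a FASTA path, DNAStringSet, or named character vector")
  }
  toupper(genome)
}

## Split 20-mers into a 20 x n character matrix (one column per guide).
guide_char_matrix <- function(seqs) {
  stopifnot(all(nchar(seqs) == 20L))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = 20L)
}

check_guide_alphabet <- function(seqs, what = "guide sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(utils::head(seqs[bad], 3L), collapse = ", ")))
  }
  badlen <- nchar(seqs) != 20L
  if (any(badlen)) {
    stop(sprintf("%s must be 20 nt long (got length %s for %s)", what,
                 nchar(seqs[badlen][1L]), seqs[badlen][1L]))
  }
  invisible(seqs)
}

#' @importFrom methods is
NULL
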