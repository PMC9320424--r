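#' @importFrom methods new validObject is slot
#' @importFrom stats setNames rnorm runif rbinom rpois dnorm p.adjust
#'   wilcox.test shapiro.test phyper fisher.test ks.test quantile
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcompStr <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste(unname(COMPLEMENT[ch]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## integer codes 1..4 for A,C,G,T; NA otherwise
dnaCodes <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
}

codesToStr <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Convert 0-based half-open intervals to 1-based inclusive (and back)
#'
#' BED-style records are 0-based half-open; variants and FASTA fetches are
#' 1-based inclusive. All conversions in the package go through these two
#' helpers.
#'
#' @param start,end interval bounds in the source convention.
#' @return a list with `start` and `end` in the target convention.
#' @export
bedToOneBased <- function(start, end) {
  stopifnot(all(start < end))
  list(start = start + 1L, end = end)
}

#' @rdname bedToOneBased
#' @export
oneBasedToBed <- function(start, end) {
  stopifnot(all(start <= end))
  list(start = start - 1L, end = end)
}

## all k-mers over ACGT in lexicographic order ("" for k = 0)
allKmers <- function(k) {
  if (k == 0) return("")
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  # lexicographic: first character most significant
  apply(as.matrix(g[, rev(seq_len(k)), drop = FALSE]), 1L, paste, collapse = "")
}

## named character -> DNAStringSet-agnostic sequence accessor
chromSeq <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) {
      stop("unknown chromosome: ", chrom)
    }
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) {
      stop("unknown chromosome: ", chrom)
    }
    return(unname(genome[[chrom]]))
  }
  stop("genome must be a named character vector or a DNAStringSet")
}

stopifnotCols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
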