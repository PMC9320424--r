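#' PWMotif: a position weight matrix for one transcription factor
#'
#' Stores raw per-position base counts (or weights) for a motif, as parsed
#' from JASPAR- or TRANSFAC-style libraries. Rows are the four bases
#' A, C, G, T; columns are motif positions. Counts are converted to
#' per-column frequencies with [pwmFrequencies()] before scanning.
#'
#' @slot matrixId character, library identifier (e.g. "MA0095.2").
#' @slot tfName character, transcription factor name.
#' @slot counts numeric 4 x L matrix, non-negative, rownames A/C/G/T; each
#'   column must have at least one positive entry.
#' @slot sourceDb character, origin database label.
#' @export
setClass("PWMotif",
  representation(
    matrixId = "character",
    tfName = "character",
    counts = "matrix",
    sourceDb = "character"
  )
)

setValidity("PWMotif", function(object) {
  cnt <- object@counts
  if (!is.numeric(cnt)) return("counts must be numeric")
  if (nrow(cnt) != 4L) return("counts must have 4 rows (A, C, G, T)")
  if (!identical(rownames(cnt), DNA_BASES)) {
    return("counts rownames must be A, C, G, T")
  }
  if (ncol(cnt) < 1L) return("motif length must be >= 1")
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    return("counts must be finite and non-negative")
  }
  if (any(colSums(cnt) <= 0)) {
    return("every motif column needs at least one positive count")
  }
  TRUE
})

#' Construct a PWMotif
#'
#' @param matrixId,tfName,sourceDb identifier strings.
#' @param counts 4 x L non-negative numeric matrix (rows A, C, G, T).
#' @return a [PWMotif-class] object.
#' @examples
#' m <- PWMotif("M1", "TF1", matrix(c(8, 0, 0, 0), 4, 3,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)) + c(0, 1, 1, 1))
#' motifLength(m)
#' @export
PWMotif <- function(matrixId, tfName, counts, sourceDb = "unknown") {
  counts <- as.matrix(counts)
  rownames(counts) <- DNA_BASES
  new("PWMotif", matrixId = as.character(matrixId),
      tfName = as.character(tfName), counts = counts,
      sourceDb = as.character(sourceDb))
}

#' @describeIn PWMotif library identifier accessor
#' @param x a PWMotif
#' @export
motifId <- function(x) x@matrixId

#' @describeIn PWMotif transcription factor name accessor
#' @export
tfName <- function(x) x@tfName

#' @describeIn PWMotif raw count matrix accessor
#' @export
motifCounts <- function(x) x@counts

#' @describeIn PWMotif motif length (number of columns)
#' @export
motifLength <- function(x) ncol(x@counts)

#' Total information content of a motif (bits)
#'
#' Computed from the count-normalized column frequencies without
#' pseudocounts: `sum over columns of (2 + sum f * log2 f)`. Because it
#' only depends on the multiset of values within each column, it is exactly
#' conserved by [permuteMatrix()].
#'
#' @param x a [PWMotif-class] or a 4 x L numeric matrix.
#' @return total information content in bits.
#' @export
informationContent <- function(x) {
  cnt <- if (methods::is(x, "PWMotif")) x@counts else as.matrix(x)
  f <- sweep(cnt, 2L, colSums(cnt), "/")
  h <- ifelse(f > 0, f * log2(f), 0)
  sum(2 + colSums(h))
}

#' Consensus sequence of a motif (maximum-count base per column)
#' @param x a [PWMotif-class].
#' @return character consensus string.
#' @export
motifConsensus <- function(x) {
  paste(DNA_BASES[apply(x@counts, 2L, which.max)], collapse = "")
}

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@matrixId, "(", object@tfName, ")",
      "L =", motifLength(object),
      sprintf("IC = %.1f bits", informationContent(object)),
      "\n consensus:", motifConsensus(object), "\n")
})

#' MarkovBackground: an order-k Markov sequence model
#'
#' Background model for motif scanning. `transitions[ctx, b]` is the
#' probability of base `b` given the preceding k-mer `ctx`; `stationary`
#' is the marginal distribution over contexts. Estimated from training
#' sequences with [estimateMarkov()]; order 2 captures CpG depletion.
#'
#' @slot order integer >= 0.
#' @slot transitions numeric 4^k x 4 matrix, rows sum to 1, rownames are
#'   the k-mers (a single "" row for order 0), colnames A/C/G/T.
#' @slot stationary named numeric over the same contexts, sums to 1.
#' @slot label character set label ("a".."d", "global", ...).
#' @slot pseudocount numeric, pseudocount used during estimation.
#' @export
setClass("MarkovBackground",
  representation(
    order = "integer",
    transitions = "matrix",
    stationary = "numeric",
    label = "character",
    pseudocount = "numeric"
  )
)

setValidity("MarkovBackground", function(object) {
  k <- object@order
  if (length(k) != 1L || k < 0L) return("order must be a single integer >= 0")
  tr <- object@transitions
  if (nrow(tr) != 4^k) return("transitions must have 4^order rows")
  if (!identical(colnames(tr), DNA_BASES)) {
    return("transitions colnames must be A, C, G, T")
  }
  if (any(abs(rowSums(tr) - 1) > 1e-9)) {
    return("each context's next-base probabilities must sum to 1")
  }
  if (any(tr < 0)) return("transition probabilities must be non-negative")
  st <- object@stationary
  if (length(st) != nrow(tr)) return("stationary length must match contexts")
  if (abs(sum(st) - 1) > 1e-9) return("stationary must sum to 1")
  if (!identical(names(st), rownames(tr))) {
    return("stationary names must match transition rownames")
  }
  TRUE
})

#' @describeIn MarkovBackground model order accessor
#' @param x a MarkovBackground
#' @export
bgOrder <- function(x) x@order

#' @describeIn MarkovBackground transition matrix accessor
#' @export
bgTransitions <- function(x) x@transitions

#' @describeIn MarkovBackground stationary context distribution accessor
#' @export
bgStationary <- function(x) x@stationary

#' @describeIn MarkovBackground set label accessor
#' @export
bgLabel <- function(x) x@label

setMethod("show", "MarkovBackground", function(object) {
  cat("MarkovBackground order", object@order,
      "label", object@label,
      "pseudocount", object@pseudocount, "\n")
  cat(" contexts:", nrow(object@transitions), "\n")
})
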