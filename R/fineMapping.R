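#' Filter association records by genome-wide significance
#'
#' @param records data.frame with at least `p_value`.
#' @param alpha significance threshold; records with `p_value <= alpha`
#'   are kept, default genome-wide significance 5e-8.
#' @return the significant subset, input order preserved.
#' @export
filterGenomewideSignificant <- function(records, alpha = 5e-8) {
  stopifnotCols(records, "p_value", "association table")
  if (any(records$p_value <= 0 | records$p_value > 1)) {
    stop("p_value must lie in (0, 1]")
  }
  records[records$p_value <= alpha, , drop = FALSE]
}

#' LD-expand an index variant into a locus
#'
#' Collects all variants whose r-squared with the index reaches
#' `r2_min`, plus the index itself at r2 = 1.
#'
#' @param index_variant variant id of the locus index.
#' @param ld_records data.frame with variant_a, variant_b, r2 (pairs are
#'   treated symmetrically).
#' @param r2_min membership threshold (default 0.5).
#' @return a locus: list with `index`, and `members` data.frame
#'   (variant_id, r2) sorted by decreasing r2, index first.
#' @export
ldExpand <- function(index_variant, ld_records, r2_min = 0.5) {
  stopifnotCols(ld_records, c("variant_a", "variant_b", "r2"), "LD table")
  hit_a <- ld_records$variant_a == index_variant
  hit_b <- ld_records$variant_b == index_variant
  partners <- data.frame(
    variant_id = c(ld_records$variant_b[hit_a], ld_records$variant_a[hit_b]),
    r2 = c(ld_records$r2[hit_a], ld_records$r2[hit_b]),
    stringsAsFactors = FALSE)
  partners <- partners[partners$variant_id != index_variant, , drop = FALSE]
  if (nrow(partners)) { # best r2 per partner if duplicated
    partners <- partners[order(-partners$r2), , drop = FALSE]
    partners <- partners[!duplicated(partners$variant_id), , drop = FALSE]
    partners <- partners[partners$r2 >= r2_min, , drop = FALSE]
  } else {
    warning("index variant ", index_variant, " absent from the LD table; ",
            "locus of size 1")
  }
  members <- rbind(
    data.frame(variant_id = index_variant, r2 = 1, stringsAsFactors = FALSE),
    partners)
  members <- members[order(-members$r2,
                           members$variant_id != index_variant), ,
                     drop = FALSE]
  rownames(members) <- NULL
  list(locus_id = index_variant, index = index_variant, members = members)
}

#' PICS-style causal probabilities for one locus
#'
#' Implements a Gaussian fine-mapping approximation: with the index
#' association strength `S = -log10(p_index)`, a member at LD `r2` is
#' expected to carry association `mu = r2 * S` with spread
#' `sigma = k * sqrt(S) * sqrt(1 - r^c)`, `r = sqrt(r2)`. The causal
#' probability of each member is proportional to the Gaussian density of
#' the observed index association under that member being causal, and is
#' normalized across the locus. Members in perfect LD with the index
#' (`sigma` below the floor) share the probability mass equally.
#'
#' @param locus a locus as returned by [ldExpand()].
#' @param index_logp -log10 of the index p-value (> 0).
#' @param k,c positive shape constants (defaults 0.5 and 3.2).
#' @param sigma_floor lower bound on sigma to avoid division by zero at
#'   r2 = 1.
#' @return data.frame (variant_id, r2, pics_prob), probabilities summing
#'   to 1; the index variant attains the maximum.
#' @export
picsProbabilities <- function(locus, index_logp, k = 0.5, c = 3.2,
                              sigma_floor = 1e-6) {
  stopifnot(index_logp > 0, k > 0, c > 0)
  members <- locus$members
  if (nrow(members) == 1L) {
    return(data.frame(variant_id = members$variant_id, r2 = members$r2,
                      pics_prob = 1, stringsAsFactors = FALSE))
  }
  S <- index_logp
  r <- sqrt(pmin(pmax(members$r2, 0), 1))
  sigma <- pmax(k * sqrt(S) * sqrt(pmax(1 - r^c, 0)), sigma_floor)
  # members at r2 = 1 share the mass equally via identical floored sigma
  dens <- dnorm(S, mean = members$r2 * S, sd = sigma)
  if (sum(dens) == 0) dens <- rep(1, length(dens))
  data.frame(variant_id = members$variant_id, r2 = members$r2,
             pics_prob = dens / sum(dens), stringsAsFactors = FALSE)
}

#' Filter PICS records by causal probability
#'
#' Retains records with `pics_prob` strictly greater than the threshold
#' ("greater than 10 percent").
#'
#' @param records data.frame with `pics_prob`.
#' @param threshold strict lower bound, default 0.10.
#' @return the retained subset.
#' @export
filterPics <- function(records, threshold = 0.10) {
  stopifnotCols(records, "pics_prob", "PICS table")
  records[records$pics_prob > threshold, , drop = FALSE]
}
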