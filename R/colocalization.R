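#' Overlap GWAS and eQTL PICS causal sets
#'
#' A candidate colocalization pair is a (variant, eGene, tissue)
#' combination where the variant's causal probability exceeds the
#' threshold in both the GWAS and the eQTL fine-mapping.
#'
#' @param gwas_records,eqtl_records PICS data.frames (variant_id,
#'   pics_prob; eQTL records also carry egene and tissue).
#' @param threshold strict PICS probability cutoff applied to both
#'   sources (default 0.10).
#' @return data.frame (variant_id, egene, tissue, gwas_pics, eqtl_pics,
#'   clpp), one row per candidate, with `clpp` the product of the two
#'   probabilities.
#' @export
overlapPics <- function(gwas_records, eqtl_records, threshold = 0.10) {
  stopifnotCols(gwas_records, c("variant_id", "pics_prob"), "GWAS PICS")
  stopifnotCols(eqtl_records, c("variant_id", "pics_prob", "egene", "tissue"),
                "eQTL PICS")
  g <- filterPics(gwas_records, threshold)
  e <- filterPics(eqtl_records, threshold)
  if (!nrow(g) || !nrow(e)) {
    return(data.frame(variant_id = character(), egene = character(),
                      tissue = character(), gwas_pics = numeric(),
                      eqtl_pics = numeric(), clpp = numeric()))
  }
  # best GWAS probability per variant (a variant can appear in one locus only,
  # but snapshot tables occasionally duplicate rows)
  g <- g[order(-g$pics_prob), , drop = FALSE]
  g <- g[!duplicated(g$variant_id), , drop = FALSE]
  m <- merge(e, g[, c("variant_id", "pics_prob")], by = "variant_id",
             suffixes = c("_eqtl", "_gwas"))
  out <- data.frame(variant_id = m$variant_id, egene = m$egene,
                    tissue = m$tissue,
                    gwas_pics = m$pics_prob_gwas,
                    eqtl_pics = m$pics_prob_eqtl,
                    stringsAsFactors = FALSE)
  out$clpp <- clpp(out$gwas_pics, out$eqtl_pics)
  out[order(-out$clpp, out$variant_id, out$egene, out$tissue), , drop = FALSE]
}

#' Colocalization posterior probability (CLPP)
#'
#' Product of the GWAS and eQTL causal probabilities, assuming
#' independence of the two fine-mappings.
#'
#' @param gwas_p,eqtl_p probabilities in \[0, 1\] (vectorized).
#' @return elementwise product.
#' @examples
#' clpp(0.5, 0.4) # 0.2
#' @export
clpp <- function(gwas_p, eqtl_p) {
  if (any(gwas_p < 0 | gwas_p > 1) || any(eqtl_p < 0 | eqtl_p > 1)) {
    stop("CLPP factors must lie in [0, 1]")
  }
  gwas_p * eqtl_p
}

#' Deduplicate colocalization pairs to the best tissue per variant-eGene
#'
#' Headline counts are per (variant, eGene); the full per-tissue detail is
#' what [overlapPics()] returns.
#'
#' @param pairs data.frame from [overlapPics()].
#' @return subset with the maximum-CLPP tissue per (variant_id, egene).
#' @export
dedupeColocPairs <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  pairs <- pairs[order(-pairs$clpp), , drop = FALSE]
  keep <- !duplicated(pairs[, c("variant_id", "egene")])
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided Fisher enrichment of GWAS causal variants in eQTL regions
#'
#' Hypergeometric upper tail: the probability of observing at least
#' `k_overlap` eQTL variants among `n_gwas` draws from a universe of
#' `n_universe` variants of which `n_eqtl_universe` are eQTLs. Identical
#' to a one-sided ("greater") Fisher exact test on the 2x2 table.
#'
#' @param k_overlap observed overlap count.
#' @param n_gwas number of GWAS causal variants.
#' @param n_eqtl_universe number of eQTL variants in the universe.
#' @param n_universe universe size.
#' @return the one-sided p-value.
#' @export
enrichmentFisher <- function(k_overlap, n_gwas, n_eqtl_universe, n_universe) {
  if (k_overlap > min(n_gwas, n_eqtl_universe) ||
      n_gwas > n_universe || n_eqtl_universe > n_universe ||
      k_overlap < max(0, n_gwas + n_eqtl_universe - n_universe) ||
      any(c(k_overlap, n_gwas, n_eqtl_universe, n_universe) < 0)) {
    stop("inconsistent 2x2 counts")
  }
  phyper(k_overlap - 1, n_eqtl_universe, n_universe - n_eqtl_universe,
         n_gwas, lower.tail = FALSE)
}
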