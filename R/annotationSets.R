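#' Default consequence-term to set mapping
#'
#' Maps Sequence-Ontology-style consequence terms onto the four scanning
#' sets: (a) intergenic and UTR, (b) intronic, (c) regulatory,
#' (d) non-coding transcript. Shipped as an editable default; unmapped
#' terms are logged and ignored.
#'
#' The shipped copy lives at
#' `system.file("extdata", "term_set_map.tsv", package = "regvar")`;
#' pass an edited file to use a different mapping.
#'
#' @param path TSV file with columns `term` and `set`.
#' @return data.frame with columns `term` and `set`.
#' @export
defaultTermSetMap <- function(path = system.file("extdata",
                                                 "term_set_map.tsv",
                                                 package = "regvar")) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Assign variants to consequence sets
#'
#' A variant's sets are the union of the sets its consequence terms map
#' to; a variant may belong to several sets and is then scanned once per
#' set.
#'
#' @param variants data.frame with `variant_id` and `consequence_terms`
#'   (comma-joined term strings).
#' @param term_map data.frame term -> set (default [defaultTermSetMap()]).
#' @return data.frame (variant_id, set), one row per assignment; variants
#'   with no mapped term are absent (a warning lists unmapped terms).
#' @export
assignConsequenceSets <- function(variants, term_map = defaultTermSetMap()) {
  stopifnotCols(variants, c("variant_id", "consequence_terms"), "variants")
  terms <- strsplit(variants$consequence_terms, ",", fixed = TRUE)
  terms <- lapply(terms, trimws)
  long <- data.frame(
    variant_id = rep(variants$variant_id, lengths(terms)),
    term = unlist(terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  long <- long[nzchar(long$term), , drop = FALSE]
  long$set <- term_map$set[match(long$term, term_map$term)]
  unmapped <- unique(long$term[is.na(long$set)])
  if (length(unmapped)) {
    warning("unmapped consequence term(s): ", paste(unmapped, collapse = ", "))
  }
  long <- long[!is.na(long$set), c("variant_id", "set")]
  long <- unique(long)
  rownames(long) <- NULL
  long[order(long$variant_id, long$set), , drop = FALSE]
}

#' Proximal gene (pGene) assignment
#'
#' Genes whose span extended by `window` bp on both sides contains the
#' variant position; the boundary is inclusive at exactly `window` bp.
#'
#' @param variants data.frame with variant_id, chrom, pos (1-based).
#' @param genes data.frame with gene_id, chrom, start, end (1-based
#'   inclusive).
#' @param window flank in bp (default 5000).
#' @return data.frame (variant_id, gene_id), one row per assignment.
#' @export
pgeneAssignment <- function(variants, genes, window = 5000) {
  stopifnotCols(variants, c("variant_id", "chrom", "pos"), "variants")
  stopifnotCols(genes, c("gene_id", "chrom", "start", "end"), "genes")
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(1, genes$start - window),
                                                genes$end + window))
  hits <- GenomicRanges::findOverlaps(vr, gr)
  data.frame(
    variant_id = variants$variant_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
}

#' Flag potentially pathogenic variants by CADD PHRED score
#'
#' @param variants data.frame with `variant_id` and `cadd_phred` (missing
#'   scores leave the variant unflagged, with a message).
#' @param cutoff inclusive threshold, default 15.
#' @return the flagged subset of `variants`.
#' @export
caddFlag <- function(variants, cutoff = 15) {
  stopifnotCols(variants, "cadd_phred", "variants")
  missing <- is.na(variants$cadd_phred)
  if (any(missing)) {
    message(sum(missing), " variant(s) without CADD score left unflagged")
  }
  variants[!missing & variants$cadd_phred >= cutoff, , drop = FALSE]
}
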