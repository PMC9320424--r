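#' The 18-state ChromHMM vocabulary and the active subset
#'
#' @return character vector of state labels.
#' @export
chromhmmStates <- function() {
  c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
    "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF/Rpts",
    "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

#' @rdname chromhmmStates
#' @export
activeChromhmmStates <- function() {
  c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
    "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF/Rpts")
}

#' Restrict variants to active chromatin in selected biosamples
#'
#' A variant is retained when its single-base position overlaps at least
#' one segment whose state is active in at least one of the selected
#' biosamples. Segments are 0-based half-open, so a variant at a segment's
#' `end` coordinate is not covered by it.
#'
#' @param variants data.frame with variant_id, chrom, pos (1-based).
#' @param segments data.frame with chrom, start, end (0-based half-open),
#'   name (state label) and biosample.
#' @param active_states state labels treated as active (default
#'   [activeChromhmmStates()]).
#' @param biosamples biosample names to consult (default all present).
#' @return the retained subset of `variants`.
#' @export
activeRegionFilter <- function(variants, segments,
                               active_states = activeChromhmmStates(),
                               biosamples = NULL) {
  stopifnotCols(variants, c("variant_id", "chrom", "pos"), "variants")
  stopifnotCols(segments, c("chrom", "start", "end", "name"), "segments")
  unknown <- setdiff(unique(segments$name), chromhmmStates())
  if (length(unknown)) {
    stop("unknown chromatin state label(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(biosamples)) {
    stopifnotCols(segments, "biosample", "segments")
    segments <- segments[segments$biosample %in% biosamples, , drop = FALSE]
  }
  segments <- segments[segments$name %in% active_states, , drop = FALSE]
  if (!nrow(segments) || !nrow(variants)) {
    return(variants[integer(0), , drop = FALSE])
  }
  conv <- bedToOneBased(segments$start, segments$end)
  sr <- GenomicRanges::GRanges(segments$chrom,
                               IRanges::IRanges(conv$start, conv$end))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  hit <- GenomicRanges::countOverlaps(vr, sr) > 0
  variants[hit, , drop = FALSE]
}

#' Filter transcription factors by expression
#'
#' Retains TFs with TPM at or above the threshold in at least one of the
#' selected tissues. TFs missing from the matrix are retained with a
#' warning by default (set `keep_unresolved = FALSE` to drop them).
#'
#' @param tf_names character vector of TF gene names.
#' @param expression numeric matrix genes x tissues (TPM).
#' @param threshold inclusive TPM cutoff (default 2).
#' @param tissues tissue columns to consult (non-empty).
#' @param keep_unresolved keep TFs absent from the matrix (default TRUE).
#' @return the retained subset of `tf_names`.
#' @export
tfExpressionFilter <- function(tf_names, expression, threshold = 2,
                               tissues = colnames(expression),
                               keep_unresolved = TRUE) {
  if (!length(tissues)) stop("empty tissue selection")
  missing_t <- setdiff(tissues, colnames(expression))
  if (length(missing_t)) {
    stop("tissue(s) absent from the expression matrix: ",
         paste(missing_t, collapse = ", "))
  }
  resolved <- tf_names %in% rownames(expression)
  if (any(!resolved)) {
    warning("TF(s) not in the expression matrix: ",
            paste(unique(tf_names[!resolved]), collapse = ", "))
  }
  keep <- logical(length(tf_names))
  keep[!resolved] <- keep_unresolved
  if (any(resolved)) {
    sub <- expression[tf_names[resolved], tissues, drop = FALSE]
    keep[resolved] <- apply(sub, 1L, function(x) any(x >= threshold))
  }
  tf_names[keep]
}

#' Default tissue-equivalence map for brain biosamples
#'
#' Links the three tissue vocabularies the pipeline touches: eQTL tissue
#' names (GTEx style), TF-target tissue names and chromatin biosample
#' names. Rows with the same `group` are considered equivalent. Shipped
#' as an editable default.
#'
#' The shipped copy lives at
#' `system.file("extdata", "tissue_map.tsv", package = "regvar")`; pass an
#' edited file to use different equivalences.
#'
#' @param path TSV file with columns group, eqtl_tissue, tftarget_tissue,
#'   biosample.
#' @return data.frame (group, eqtl_tissue, tftarget_tissue, biosample).
#' @export
defaultTissueMap <- function(path = system.file("extdata", "tissue_map.tsv",
                                                package = "regvar")) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

tissuesEquivalent <- function(eqtl_tissue, tftarget_tissue, tissue_map) {
  ge <- tissue_map$group[match(eqtl_tissue, tissue_map$eqtl_tissue)]
  gt <- tissue_map$group[match(tftarget_tissue, tissue_map$tftarget_tissue)]
  !is.na(ge) & !is.na(gt) & ge == gt
}

#' Assemble variant -> TF -> eGene mechanistic evidence triples
#'
#' A triple is emitted when a confirmed (variant, TF) binding-alteration
#' pair coincides with an eQTL record linking the same variant to an
#' eGene in tissue T1, and a TF-target record linking the same TF to that
#' eGene in tissue T2, with T1 and T2 equivalent under the tissue map.
#'
#' @param confirmed_pairs data.frame with variant_id, tf_name (and
#'   optionally matrix_id, effect carried through).
#' @param eqtl_records eQTL PICS data.frame (variant_id, egene, tissue),
#'   already filtered to the causal set.
#' @param tftarget_records data.frame (tf_name, target_gene, tissue).
#' @param tissue_map equivalence table (default [defaultTissueMap()]).
#' @return data.frame (variant_id, tf_name, egene, eqtl_tissue,
#'   tftarget_tissue, provenance), one row per supported triple.
#' @export
mechanisticEvidence <- function(confirmed_pairs, eqtl_records,
                                tftarget_records,
                                tissue_map = defaultTissueMap()) {
  stopifnotCols(confirmed_pairs, c("variant_id", "tf_name"),
                "confirmed pairs")
  stopifnotCols(eqtl_records, c("variant_id", "egene", "tissue"),
                "eQTL records")
  stopifnotCols(tftarget_records, c("tf_name", "target_gene", "tissue"),
                "TF-target records")
  empty <- data.frame(variant_id = character(), tf_name = character(),
                      egene = character(), eqtl_tissue = character(),
                      tftarget_tissue = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  if (!nrow(confirmed_pairs) || !nrow(eqtl_records) ||
      !nrow(tftarget_records)) return(empty)
  pairs <- unique(confirmed_pairs[, c("variant_id", "tf_name")])
  m1 <- merge(pairs, eqtl_records[, c("variant_id", "egene", "tissue")],
              by = "variant_id")
  names(m1)[names(m1) == "tissue"] <- "eqtl_tissue"
  if (!nrow(m1)) return(empty)
  m2 <- merge(m1, tftarget_records,
              by.x = c("tf_name", "egene"),
              by.y = c("tf_name", "target_gene"))
  names(m2)[names(m2) == "tissue"] <- "tftarget_tissue"
  if (!nrow(m2)) return(empty)
  ok <- tissuesEquivalent(m2$eqtl_tissue, m2$tftarget_tissue, tissue_map)
  m2 <- m2[ok, , drop = FALSE]
  if (!nrow(m2)) return(empty)
  out <- data.frame(
    variant_id = m2$variant_id, tf_name = m2$tf_name, egene = m2$egene,
    eqtl_tissue = m2$eqtl_tissue, tftarget_tissue = m2$tftarget_tissue,
    provenance = paste("eqtl", m2$variant_id, m2$egene, m2$eqtl_tissue,
                       "tftarget", m2$tf_name, m2$egene, m2$tftarget_tissue,
                       sep = ":"),
    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$variant_id, out$tf_name, out$egene), , drop = FALSE]
}
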