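#' Default pipeline parameters
#'
#' Every threshold of the analysis in one editable list: genome-wide
#' significance alpha, PICS and CLPP probability cutoffs, the four scan
#' retention thresholds, the control ratios, the rank-test alpha, the TPM
#' and CADD cutoffs, and the numerical settings of the scanner.
#'
#' @param ... overrides for any default.
#' @return named list of parameters.
#' @export
pipelineParams <- function(...) {
  p <- list(
    alpha = 5e-8,            # genome-wide significance
    r2_min = 0.5,            # LD-expansion membership
    pics_threshold = 0.10,   # strict, "greater than 10%"
    clpp_threshold = 0.10,   # strict
    flank = 30L,             # bases per side of each variant window
    bg_order = 2L,           # Markov background order (CpG-aware)
    bg_pseudocount = 1,
    min_bg_bp = 10000,       # per-set training floor before global fallback
    pwm_pseudocount = 1,
    bin = 0.01,              # score grid (log2 units)
    weight_min = 1,
    weight_diff_min = 1,
    pvalue_max = 1e-3,
    ratio_min = 10,
    n_perm = 5L,             # permuted replicates per matrix
    ratios = c(10L, 1000L),  # matched-control ratios (strict, relaxed)
    wilcoxon_alpha = 0.05,
    confirm_method = "quantile", # or "wilcoxon" (motif-level rank test)
    tpm_threshold = 2,
    cadd_cutoff = 15,
    pics_source = "table",   # "table" (snapshot) or "internal"
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p
}

## per-set background models trained on the peak sequences overlapping each
## set's variants, with a pooled global fallback for thin sets
buildSetBackgrounds <- function(inputs, sets, scan_variants, params) {
  peaks <- inputs$peaks
  conv <- bedToOneBased(peaks$start, peaks$end)
  peak_seq <- vapply(seq_len(nrow(peaks)), function(i)
    fetchSequence(inputs$genome, peaks$chrom[i], conv$start[i], conv$end[i]),
    character(1))
  pr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(conv$start, conv$end))
  global <- estimateMarkov(peak_seq, params$bg_order, params$bg_pseudocount,
                           label = "global")
  out <- list(global = global)
  for (s in sort(unique(sets$set))) {
    vids <- sets$variant_id[sets$set == s]
    vv <- scan_variants[scan_variants$variant_id %in% vids, , drop = FALSE]
    if (!nrow(vv)) next
    vr <- GenomicRanges::GRanges(vv$chrom, IRanges::IRanges(vv$pos, vv$pos))
    hit <- unique(S4Vectors::subjectHits(GenomicRanges::findOverlaps(vr, pr)))
    seqs <- peak_seq[hit]
    if (sum(nchar(seqs)) < params$min_bg_bp) {
      out[[s]] <- global
    } else {
      out[[s]] <- estimateMarkov(seqs, params$bg_order,
                                 params$bg_pseudocount, label = s)
    }
  }
  out
}

## scan a variant table (with windows) per consequence set, reusing score
## distributions through `cache`
scanBySet <- function(windows, sets, motifs, backgrounds, params, cache) {
  out <- list()
  for (s in sort(unique(sets$set))) {
    bg <- backgrounds[[s]]
    if (is.null(bg)) bg <- backgrounds$global
    w <- windows[windows$variant_id %in%
                   sets$variant_id[sets$set == s], , drop = FALSE]
    if (!nrow(w)) next
    res <- scanVariants(w, motifs, bg, params$pwm_pseudocount, params$bin,
                        cache)
    if (nrow(res)) res$set <- s
    out[[s]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- emptyScanFrame()
    res$set <- character(0)
  }
  rownames(res) <- NULL
  res
}

#' Run the full regulatory-variation analysis pipeline
#'
#' Stages: genome-wide significance filter, fine-mapping (precomputed PICS
#' table or internal LD expansion + PICS), eQTL colocalization with CLPP
#' and Fisher enrichment, consequence-set assignment, per-set Markov
#' backgrounds, allele-specific motif scanning with retention filters,
#' negative controls (permuted matrices; strict 1:10 and relaxed 1:1000
#' matched variants) with per-motif rank-test confirmation, chromatin
#' state and TF expression gating, and mechanistic evidence assembly.
#'
#' @param inputs list shaped like [simulateRegulatoryData()] output
#'   (or [readSimulation()]).
#' @param params list from [pipelineParams()].
#' @return list with the stage outputs (`coloc_pairs`, `scan`,
#'   `scan_pass`, `confirmation`, `final_pairs`, `evidence`, ...) and a
#'   `report` of funnel counts and settings.
#' @export
runPipeline <- function(inputs, params = pipelineParams()) {
  for (need in c("genome", "genes", "motifs", "peaks", "variants",
                 "associations", "gwas_pics", "eqtl_pics", "chromhmm",
                 "tpm", "tftarget")) {
    if (is.null(inputs[[need]])) stop("pipeline input missing: ", need)
  }
  tissue_map <- if (!is.null(inputs$tissue_map)) inputs$tissue_map else
    defaultTissueMap()
  ## 1. association filter + fine mapping
  sig <- filterGenomewideSignificant(inputs$associations, params$alpha)
  gwas_pics <- if (identical(params$pics_source, "internal")) {
    do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      locus <- ldExpand(sig$variant_id[i], inputs$ld, params$r2_min)
      pp <- picsProbabilities(locus, -log10(sig$p_value[i]))
      data.frame(variant_id = pp$variant_id, locus_id = locus$locus_id,
                 pics_prob = pp$pics_prob, source = "gwas", tissue = "",
                 egene = "", stringsAsFactors = FALSE)
    }))
  } else {
    inputs$gwas_pics[inputs$gwas_pics$locus_id %in% sig$variant_id, ,
                     drop = FALSE]
  }
  causal <- filterPics(gwas_pics, params$pics_threshold)
  ## 2. colocalization + enrichment
  coloc_all <- overlapPics(gwas_pics, inputs$eqtl_pics,
                           params$pics_threshold)
  coloc_pairs <- coloc_all[coloc_all$clpp > params$clpp_threshold, ,
                           drop = FALSE]
  coloc_headline <- dedupeColocPairs(coloc_pairs)
  universe <- unique(gwas_pics$variant_id)
  eqtl_ids <- unique(inputs$eqtl_pics$variant_id)
  n_eqtl_universe <- sum(universe %in% eqtl_ids)
  k_overlap <- sum(unique(causal$variant_id) %in% eqtl_ids)
  enrichment_p <- if (n_eqtl_universe > 0) {
    enrichmentFisher(k_overlap, length(unique(causal$variant_id)),
                     n_eqtl_universe, length(universe))
  } else NA_real_
  ## 3. annotation
  variants <- inputs$variants
  sets <- assignConsequenceSets(variants)
  pgenes <- pgeneAssignment(
    variants[variants$variant_id %in% causal$variant_id, ], inputs$genes)
  cadd_flagged <- caddFlag(
    variants[!is.na(variants$cadd_phred), , drop = FALSE],
    params$cadd_cutoff)
  ## 4. variants in peaks -> scan targets
  pconv <- bedToOneBased(inputs$peaks$start, inputs$peaks$end)
  pr <- GenomicRanges::GRanges(inputs$peaks$chrom,
                               IRanges::IRanges(pconv$start, pconv$end))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  in_peak <- GenomicRanges::countOverlaps(vr, pr) > 0
  scan_variants <- variants[in_peak, , drop = FALSE]
  backgrounds <- buildSetBackgrounds(inputs, sets, scan_variants, params)
  windows <- buildVariantWindows(inputs$genome, scan_variants, params$flank)
  cache <- new.env(parent = emptyenv())
  scan <- scanBySet(windows, sets, inputs$motifs, backgrounds, params, cache)
  scan_pass <- applyScanFilters(scan, params$weight_min,
                                params$weight_diff_min, params$pvalue_max,
                                params$ratio_min)
  ## 5. negative controls
  permuted <- unlist(lapply(seq_along(inputs$motifs), function(i) {
    permuteMatrix(inputs$motifs[[i]], params$n_perm,
                  seed = params$seed * 1000L + i)
  }), recursive = FALSE)
  perm_scan <- scanBySet(windows, sets, permuted, backgrounds, params, cache)
  perm_pass <- applyScanFilters(perm_scan, params$weight_min,
                                params$weight_diff_min, params$pvalue_max,
                                params$ratio_min)
  perm_pass$matrix_id <- sub("_perm[0-9]+$", "", perm_pass$matrix_id)
  ctrl <- list(permuted = perm_pass[, c("matrix_id", "pval_ratio")])
  if (!is.null(inputs$pool) && nrow(inputs$pool)) {
    tattr <- computeMatchAttributes(scan_variants, inputs$genes, inputs$ld)
    pattr <- computeMatchAttributes(inputs$pool, inputs$genes, inputs$ld)
    a10 <- sampleMatchedControls(tattr, pattr, "strict", params$ratios[1],
                                 seed = params$seed)
    a1000 <- sampleMatchedControls(tattr, pattr, "relaxed", params$ratios[2],
                                   seed = params$seed + 1L)
    ctl_ids <- unique(c(a10$control_variant_id, a1000$control_variant_id))
    ctl_variants <- inputs$pool[inputs$pool$variant_id %in% ctl_ids, ,
                                drop = FALSE]
    ctl_sets <- assignConsequenceSets(ctl_variants)
    ctl_windows <- buildVariantWindows(inputs$genome, ctl_variants,
                                       params$flank)
    ctl_scan <- scanBySet(ctl_windows, ctl_sets, inputs$motifs, backgrounds,
                          params, cache)
    ctl_pass <- applyScanFilters(ctl_scan, params$weight_min,
                                 params$weight_diff_min, params$pvalue_max,
                                 params$ratio_min)
    ctrl$matched10 <- ctl_pass[ctl_pass$variant_id %in%
                                 a10$control_variant_id,
                               c("matrix_id", "pval_ratio")]
    ctrl$matched1000 <- ctl_pass[ctl_pass$variant_id %in%
                                   a1000$control_variant_id,
                                 c("matrix_id", "pval_ratio")]
  } else {
    ctrl$matched10 <- ctrl$matched1000 <-
      data.frame(matrix_id = character(), pval_ratio = numeric())
  }
  confirmation <- confirmMotifPairs(
    scan_pass[, c("matrix_id", "variant_id", "pval_ratio", "tf_name",
                  "effect", "set")],
    ctrl, params$wilcoxon_alpha, params$confirm_method)
  confirmed_pairs <- confirmation$pairs
  ## normality check motivating the nonparametric route
  shapiro_p <- shapiroWilkCheck(scan_pass$pval_ratio)
  ## 6. chromatin + expression gating
  brain_bs <- intersect(unique(inputs$chromhmm$biosample),
                        tissue_map$biosample)
  if (!length(brain_bs)) brain_bs <- unique(inputs$chromhmm$biosample)
  active_variants <- activeRegionFilter(
    variants[variants$variant_id %in% confirmed_pairs$variant_id, ,
             drop = FALSE],
    inputs$chromhmm, biosamples = brain_bs)
  brain_tissues <- intersect(colnames(inputs$tpm), tissue_map$eqtl_tissue)
  if (!length(brain_tissues)) brain_tissues <- colnames(inputs$tpm)
  expressed_tfs <- tfExpressionFilter(unique(confirmed_pairs$tf_name),
                                      inputs$tpm, params$tpm_threshold,
                                      brain_tissues)
  final_pairs <- confirmed_pairs[
    confirmed_pairs$variant_id %in% active_variants$variant_id &
      confirmed_pairs$tf_name %in% expressed_tfs, , drop = FALSE]
  ## 7. mechanistic evidence
  eqtl_causal <- filterPics(inputs$eqtl_pics, params$pics_threshold)
  evidence <- mechanisticEvidence(final_pairs, eqtl_causal,
                                  inputs$tftarget, tissue_map)
  report <- list(
    n_associations = nrow(inputs$associations),
    n_significant = nrow(sig),
    n_expanded = length(unique(gwas_pics$variant_id)),
    n_causal = length(unique(causal$variant_id)),
    n_coloc_pairs = nrow(coloc_headline),
    enrichment_p = enrichment_p,
    n_pgenes = length(unique(pgenes$gene_id)),
    n_cadd_flagged = nrow(cadd_flagged),
    n_scanned_variants = nrow(scan_variants),
    n_scan_pass_pairs = nrow(scan_pass),
    n_scan_pass_variants = length(unique(scan_pass$variant_id)),
    n_confirmed_motifs = sum(confirmation$motifs$confirmed),
    n_confirmed_variants = length(unique(confirmed_pairs$variant_id)),
    n_active_variants = nrow(active_variants),
    n_expressed_tfs = length(expressed_tfs),
    n_final_pairs = nrow(final_pairs),
    n_evidence_triples = nrow(evidence),
    shapiro_p_ratio = shapiro_p,
    params = params)
  list(gwas_pics = gwas_pics, causal = causal, coloc_all = coloc_all,
       coloc_pairs = coloc_pairs, coloc_headline = coloc_headline,
       sets = sets, pgenes = pgenes, backgrounds = backgrounds,
       scan = scan, scan_pass = scan_pass, controls = ctrl,
       confirmation = confirmation, active_variants = active_variants,
       expressed_tfs = expressed_tfs, final_pairs = final_pairs,
       evidence = evidence, report = report)
}
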