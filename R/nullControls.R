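#' Permute a PWM into negative-control matrices
#'
#' Each replicate shuffles the column order and, independently, the four
#' cell values within every column. The per-column value multisets — and
#' therefore the nucleotide composition and the total information content —
#' are preserved exactly.
#'
#' @param motif a [PWMotif-class].
#' @param n_perm number of permuted replicates (default 5).
#' @param seed optional integer seed for reproducible permutation.
#' @return list of [PWMotif-class]; ids are suffixed `_permN` and the
#'   source matrix id is kept in `sourceDb` as `permuted:<id>`.
#' @export
permuteMatrix <- function(motif, n_perm = 5, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  cnt <- motif@counts
  L <- ncol(cnt)
  lapply(seq_len(n_perm), function(i) {
    perm <- cnt[, sample.int(L), drop = FALSE]
    perm <- apply(perm, 2L, function(col) col[sample.int(4L)])
    rownames(perm) <- DNA_BASES
    PWMotif(paste0(motif@matrixId, "_perm", i), motif@tfName, perm,
            paste0("permuted:", motif@matrixId))
  })
}

#' Matching attributes for control-variant sampling
#'
#' Computes, per variant: distance to the closest transcription start
#' site, gene density (genes whose TSS lies within 100 kbp), number of LD
#' partners at r-squared >= 0.1, coding class and variant type.
#'
#' @param variants data.frame with variant_id, chrom, pos, ref, alt and
#'   optionally consequence_terms (used for the coding class).
#' @param genes data.frame with gene_id, chrom, tss.
#' @param ld_records data.frame variant_a, variant_b, r2.
#' @param density_window half-width of the gene-density window in bp
#'   (default 50000, i.e. genes within 100 kbp).
#' @param ld_r2_min r-squared cutoff for counting LD partners (default 0.1).
#' @return data.frame (variant_id, chrom, tss_distance, gene_density,
#'   ld_count, coding_class, variant_type); `tss_distance` is NA when the
#'   chromosome has no annotated gene (such variants are excluded from
#'   strict matching).
#' @export
computeMatchAttributes <- function(variants, genes, ld_records,
                                   density_window = 50000,
                                   ld_r2_min = 0.1) {
  stopifnotCols(variants, c("variant_id", "chrom", "pos", "ref", "alt"),
                "variants")
  stopifnotCols(genes, c("gene_id", "chrom", "tss"), "genes")
  ld <- ld_records[ld_records$r2 >= ld_r2_min, , drop = FALSE]
  ldcnt <- table(c(ld$variant_a, ld$variant_b))
  coding_terms <- c("missense_variant", "synonymous_variant",
                    "stop_gained", "stop_lost", "start_lost",
                    "coding_sequence_variant", "frameshift_variant",
                    "inframe_insertion", "inframe_deletion")
  cterms <- if ("consequence_terms" %in% names(variants)) {
    variants$consequence_terms
  } else rep("", nrow(variants))
  n <- nrow(variants)
  tssd <- rep(NA_real_, n)
  dens <- integer(n)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    tss <- genes$tss[genes$chrom == ch]
    if (!length(tss)) next
    pos <- variants$pos[vi]
    tssd[vi] <- vapply(pos, function(p) min(abs(p - tss)), numeric(1))
    dens[vi] <- vapply(pos, function(p)
      sum(abs(tss - p) <= density_window), integer(1))
  }
  data.frame(
    variant_id = variants$variant_id,
    chrom = variants$chrom,
    tss_distance = tssd,
    gene_density = dens,
    ld_count = as.integer(ifelse(is.na(match(variants$variant_id,
                                             names(ldcnt))), 0L,
                                 ldcnt[variants$variant_id])),
    coding_class = ifelse(vapply(strsplit(cterms, ","), function(t)
      any(trimws(t) %in% coding_terms), logical(1)), "coding", "non-coding"),
    variant_type = ifelse(nchar(variants$ref) == 1L &
                            nchar(variants$alt) == 1L, "SNV", "other"),
    stringsAsFactors = FALSE)
}

#' Sample matched control variants
#'
#' Strict mode matches all five attributes: TSS distance within +/- 5000
#' bp, gene density within +/- 5 (per 100 kbp), LD-partner count within
#' +/- 50 (at r-squared >= 0.1), plus coding-class and variant-type
#' equality, sampling on the target's chromosome. Relaxed mode matches
#' coding class and variant type only and samples across chromosomes.
#' Input (target) variants are always excluded from the pool; sampling is
#' without replacement per target. When fewer than `ratio` eligible
#' controls exist, all of them are taken and the shortfall is logged.
#'
#' @param target_attrs,pool_attrs attribute data.frames from
#'   [computeMatchAttributes()].
#' @param mode `"strict"` or `"relaxed"`.
#' @param ratio controls per target (10 and 1000 are the conventional
#'   ratios).
#' @param seed integer seed.
#' @param tss_window,density_window,ld_window strict matching half-widths.
#' @return data.frame (target_variant_id, control_variant_id, mode); a
#'   target with zero eligible controls is flagged in the `unmatched`
#'   attribute of the result.
#' @export
sampleMatchedControls <- function(target_attrs, pool_attrs,
                                  mode = c("strict", "relaxed"),
                                  ratio = 10, seed = 1,
                                  tss_window = 5000, density_window = 5,
                                  ld_window = 50) {
  mode <- match.arg(mode)
  set.seed(seed)
  pool <- pool_attrs[!pool_attrs$variant_id %in% target_attrs$variant_id, ,
                     drop = FALSE]
  out <- vector("list", nrow(target_attrs))
  unmatched <- character(0)
  shortfall <- 0L
  for (i in seq_len(nrow(target_attrs))) {
    t <- target_attrs[i, ]
    elig <- pool$coding_class == t$coding_class &
      pool$variant_type == t$variant_type
    if (mode == "strict") {
      if (is.na(t$tss_distance)) {
        unmatched <- c(unmatched, t$variant_id)
        next
      }
      elig <- elig & pool$chrom == t$chrom &
        !is.na(pool$tss_distance) &
        abs(pool$tss_distance - t$tss_distance) <= tss_window &
        abs(pool$gene_density - t$gene_density) <= density_window &
        abs(pool$ld_count - t$ld_count) <= ld_window
    }
    cand <- pool$variant_id[which(elig)]
    if (!length(cand)) {
      unmatched <- c(unmatched, t$variant_id)
      next
    }
    take <- min(ratio, length(cand))
    if (take < ratio) shortfall <- shortfall + (ratio - take)
    pick <- if (length(cand) == 1L) cand else sample(cand, take)
    out[[i]] <- data.frame(target_variant_id = t$variant_id,
                           control_variant_id = pick, mode = mode,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(target_variant_id = character(),
                      control_variant_id = character(),
                      mode = character(), stringsAsFactors = FALSE)
  }
  if (length(unmatched)) {
    message(length(unmatched), " target(s) had no eligible control")
  }
  if (shortfall > 0) {
    message("control shortfall of ", shortfall,
            " draw(s) against the requested ratio ", ratio)
  }
  attr(res, "unmatched") <- unmatched
  res
}

#' One-sided Wilcoxon rank-sum test ("observed greater than control")
#'
#' Exact enumeration when the pooled sample is small (n + m <= 12) and
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param observed,control numeric vectors (non-empty).
#' @return one-sided p-value.
#' @export
wilcoxonGreater <- function(observed, control) {
  stopifnot(length(observed) > 0, length(control) > 0)
  tie_free <- !anyDuplicated(c(observed, control))
  exact <- tie_free && (length(observed) + length(control)) <= 12
  suppressWarnings(
    wilcox.test(observed, control, alternative = "greater",
                exact = exact, correct = TRUE)$p.value)
}

#' Shapiro-Wilk normality check
#'
#' Used only to justify the nonparametric route in reports. Degenerate
#' (constant) samples and samples of fewer than 3 values return NA.
#'
#' @param values numeric vector.
#' @return the Shapiro-Wilk p-value, or NA when not applicable.
#' @export
shapiroWilkCheck <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L) return(NA_real_)
  if (length(unique(values)) == 1L) return(NA_real_)
  shapiro.test(values)$p.value
}

#' Confirm motifs against the negative-control systems
#'
#' For every motif, tests with a one-sided rank-sum whether the observed
#' p-value ratios stochastically dominate the control ratios of (1) the
#' permuted-matrix system and (2) the 1:10 matched-variant system; motifs
#' passing both are re-confirmed against the 1:1000 matched-variant
#' system. Confirmed pairs are the observed pairs of confirmed motifs.
#' Benjamini-Hochberg adjusted p-values are reported alongside; the
#' confirmation decision uses the raw alpha.
#'
#' Two decision rules are available. `"wilcoxon"` confirms at the motif
#' level: a motif is confirmed when its observed ratios dominate the
#' controls, and confirmation extends to all its observed pairs.
#' `"quantile"` (the default) confirms at the pair level: a pair is
#' confirmed when its own ratio exceeds the `1 - alpha` quantile of the
#' motif's control ratios in each system; a motif is confirmed when at
#' least one of its pairs is. The pair-level rule matches reporting of
#' per-variant significance counts and is robust when only a minority of
#' a motif's observed pairs carry a real effect; the motif-level
#' Wilcoxon p-values are computed and reported under both rules.
#'
#' @param observed data.frame with matrix_id, variant_id and pval_ratio
#'   (the filter-passing scan pairs).
#' @param controls named list of data.frames (`permuted`, `matched10`,
#'   `matched1000`), each with matrix_id and pval_ratio; permuted-system
#'   rows carry the source matrix id in matrix_id.
#' @param alpha raw significance level per test (default 0.05; also the
#'   upper-tail mass of the quantile rule).
#' @param method `"quantile"` or `"wilcoxon"`.
#' @return list with `motifs` (per-motif table: rank-test p-values, BH
#'   adjustments, control quantiles, stage decisions, and an
#'   `unconfirmable` flag for motifs lacking control observations) and
#'   `pairs` (the confirmed observed pairs).
#' @export
confirmMotifPairs <- function(observed, controls, alpha = 0.05,
                              method = c("quantile", "wilcoxon")) {
  method <- match.arg(method)
  stopifnotCols(observed, c("matrix_id", "variant_id", "pval_ratio"),
                "observed pairs")
  need <- c("permuted", "matched10", "matched1000")
  miss <- setdiff(need, names(controls))
  if (length(miss)) stop("missing control system(s): ",
                         paste(miss, collapse = ", "))
  ids <- sort(unique(observed$matrix_id))
  testOne <- function(id, system) {
    obs <- observed$pval_ratio[observed$matrix_id == id]
    ctl <- controls[[system]]
    ctl <- ctl$pval_ratio[ctl$matrix_id == id]
    if (!length(obs)) return(NA_real_)
    if (!length(ctl)) return(NA_real_)
    wilcoxonGreater(obs, ctl)
  }
  tab <- data.frame(
    matrix_id = ids,
    n_obs = vapply(ids, function(id) sum(observed$matrix_id == id),
                   integer(1)),
    p_permuted = vapply(ids, testOne, numeric(1), system = "permuted"),
    p_matched10 = vapply(ids, testOne, numeric(1), system = "matched10"),
    p_matched1000 = vapply(ids, testOne, numeric(1),
                           system = "matched1000"),
    stringsAsFactors = FALSE)
  tab$padj_permuted <- p.adjust(tab$p_permuted, "BH")
  tab$padj_matched10 <- p.adjust(tab$p_matched10, "BH")
  tab$padj_matched1000 <- p.adjust(tab$p_matched1000, "BH")
  tab$unconfirmable <- is.na(tab$p_permuted) | is.na(tab$p_matched10) |
    is.na(tab$p_matched1000)
  ctlQuantile <- function(id, system) {
    x <- controls[[system]]
    x <- x$pval_ratio[x$matrix_id == id]
    if (!length(x)) return(NA_real_)
    unname(quantile(x, 1 - alpha, type = 7))
  }
  tab$q_permuted <- vapply(ids, ctlQuantile, numeric(1), "permuted")
  tab$q_matched10 <- vapply(ids, ctlQuantile, numeric(1), "matched10")
  tab$q_matched1000 <- vapply(ids, ctlQuantile, numeric(1), "matched1000")
  if (method == "wilcoxon") {
    tab$stage1 <- !is.na(tab$p_permuted) & tab$p_permuted < alpha &
      !is.na(tab$p_matched10) & tab$p_matched10 < alpha
    tab$confirmed <- tab$stage1 & !is.na(tab$p_matched1000) &
      tab$p_matched1000 < alpha
    pairs <- observed[observed$matrix_id %in%
                        tab$matrix_id[tab$confirmed], , drop = FALSE]
  } else {
    qp <- tab$q_permuted[match(observed$matrix_id, tab$matrix_id)]
    q10 <- tab$q_matched10[match(observed$matrix_id, tab$matrix_id)]
    q1000 <- tab$q_matched1000[match(observed$matrix_id, tab$matrix_id)]
    stage1 <- !is.na(qp) & observed$pval_ratio > qp &
      !is.na(q10) & observed$pval_ratio > q10
    ok <- stage1 & !is.na(q1000) & observed$pval_ratio > q1000
    pairs <- observed[ok, , drop = FALSE]
    tab$stage1 <- vapply(ids, function(id)
      any(stage1[observed$matrix_id == id]), logical(1))
    tab$confirmed <- vapply(ids, function(id)
      any(ok[observed$matrix_id == id]), logical(1))
  }
  list(motifs = tab, pairs = pairs)
}
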