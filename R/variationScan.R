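#' Per-column base frequencies of a PWM
#'
#' `(count + pseudocount/4) / (column total + pseudocount)`; every column
#' sums to 1.
#'
#' @param x a [PWMotif-class] or 4 x L count matrix.
#' @param pseudocount total pseudocount per column (default 1).
#' @return 4 x L frequency matrix (rows A, C, G, T).
#' @export
pwmFrequencies <- function(x, pseudocount = 1) {
  cnt <- if (methods::is(x, "PWMotif")) x@counts else as.matrix(x)
  f <- sweep(cnt + pseudocount / 4, 2L, colSums(cnt) + pseudocount, "/")
  rownames(f) <- DNA_BASES
  f
}

#' Weight of one site under a PWM and a background model
#'
#' `log2 P(site | PWM) - log2 P(site | background)`, the background
#' conditioned on the site's preceding context (bases immediately 5' of
#' the site within its window). Log base 2 throughout.
#'
#' @param pwm_freqs 4 x L frequency matrix from [pwmFrequencies()].
#' @param bg a [MarkovBackground-class].
#' @param site_seq DNA string of length L.
#' @param context preceding bases (may be "", shorter contexts are
#'   marginalized against the stationary distribution).
#' @return the weight (log2 units); `NA` if the site contains an
#'   ambiguous base.
#' @export
siteWeight <- function(pwm_freqs, bg, site_seq, context = "") {
  L <- ncol(pwm_freqs)
  site_seq <- toupper(site_seq)
  stopifnot(nchar(site_seq) == L)
  codes <- dnaCodes(site_seq)
  if (any(is.na(codes))) {
    message("site with ambiguous base skipped: ", site_seq)
    return(NA_real_)
  }
  lp_pwm <- sum(log2(pwm_freqs[cbind(codes, seq_len(L))]))
  lp_bg <- 0
  ctx <- toupper(context)
  for (j in seq_len(L)) {
    pr <- contextConditional(bg, ctx)
    lp_bg <- lp_bg + log2(pr[[codes[j]]])
    ctx <- paste0(ctx, DNA_BASES[codes[j]])
  }
  lp_pwm - lp_bg
}

#' Exact distribution of site weights under the background
#'
#' Dynamic program over motif positions and background contexts on a
#' discretized score grid. The initial context is marginalized with the
#' stationary distribution; each step draws the next base from the
#' background and accrues the per-position weight increment
#' `log2 f - log2 P(base | context)`. Increments are rounded to `bin / 2`
#' internally, bounding the accumulated discretization error by
#' `L * bin / 4`.
#'
#' @param pwm_freqs 4 x L frequency matrix.
#' @param bg a [MarkovBackground-class].
#' @param bin score grid resolution in log2 units (default 0.01).
#' @return an object of class `weightDistribution`: list with the internal
#'   grid step `delta`, integer grid origin `min_int`, and `tail` where
#'   `tail[i] = P(weight >= (min_int + i - 1) * delta)`.
#' @export
scoreDistribution <- function(pwm_freqs, bg, bin = 0.01) {
  L <- ncol(pwm_freqs)
  k <- bg@order
  nctx <- 4^k
  delta <- bin / 2
  tr <- bg@transitions
  logtr <- log2(tr)
  logf <- log2(pwm_freqs)
  # integer score increments s_int[ctx, base] per position
  sint <- vector("list", L)
  minInc <- maxInc <- integer(L)
  for (j in seq_len(L)) {
    s <- matrix(rep(logf[, j], each = nctx), nrow = nctx) - logtr
    si <- round(s / delta)
    si[tr == 0] <- NA_integer_ # unreachable under the background
    sint[[j]] <- si
    fin <- si[is.finite(si)]
    if (!length(fin)) stop("background cannot generate any site")
    minInc[j] <- min(fin)
    maxInc[j] <- max(fin)
  }
  width <- sum(maxInc - minInc) + 1L
  min_int <- sum(minInc)
  # successor context index for (ctx, base)
  nextCtx <- outer(seq_len(nctx) - 1L, 0:3, function(ctx, b) {
    if (k == 0) rep(1L, length(ctx)) else (ctx %% 4^(k - 1)) * 4L + b + 1L
  })
  # state[bin, ctx]: column-major layout keeps the shifted adds contiguous
  state <- matrix(0, nrow = width, ncol = nctx)
  state[1L, ] <- bg@stationary
  cur <- 1L
  for (j in seq_len(L)) {
    span <- maxInc[j] - minInc[j]
    newstate <- matrix(0, nrow = width, ncol = nctx)
    for (ctx in seq_len(nctx)) {
      mass <- state[seq_len(cur), ctx]
      if (!any(mass > 0)) next
      for (b in 1:4) {
        p <- tr[ctx, b]
        si <- sint[[j]][ctx, b]
        if (p == 0 || is.na(si)) next
        sh <- si - minInc[j]
        tgt <- nextCtx[ctx, b]
        ix <- (1L + sh):(cur + sh)
        newstate[ix, tgt] <- newstate[ix, tgt] + mass * p
      }
    }
    state <- newstate
    cur <- cur + span
  }
  mass <- rowSums(state)[seq_len(cur)]
  tail <- rev(cumsum(rev(mass)))
  structure(list(delta = delta, bin = bin, min_int = min_int, tail = tail),
            class = "weightDistribution")
}

#' Tail probability P(weight >= w) from a precomputed distribution
#'
#' Right-continuous and non-increasing in `w`; `p(-Inf) = 1`. Values below
#' the grid floor are clamped to `p_floor`.
#'
#' @param dist a `weightDistribution` from [scoreDistribution()].
#' @param w weight threshold(s), vectorized.
#' @param p_floor smallest reportable p-value (default 1e-16).
#' @return tail probabilities in `[p_floor, 1]`.
#' @export
tailProbability <- function(dist, w, p_floor = 1e-16) {
  n <- length(dist$tail)
  idx <- ceiling(w / dist$delta - 1e-9) - dist$min_int + 1
  idx[w == -Inf] <- 1
  p <- numeric(length(w))
  p[idx <= 1] <- 1
  inside <- idx >= 1 & idx <= n
  p[inside] <- dist$tail[idx[inside]]
  p[idx > n] <- 0 # above the maximum achievable score
  pmin(pmax(p, p_floor), 1)
}

#' Score p-value of a weight under the background
#'
#' Convenience wrapper: builds the weight distribution with
#' [scoreDistribution()] and evaluates `P(weight >= w)`.
#'
#' @inheritParams scoreDistribution
#' @param w weight threshold(s).
#' @param p_floor smallest reportable p-value.
#' @return p-value(s) in `[p_floor, 1]`.
#' @export
weightPvalue <- function(pwm_freqs, bg, w, bin = 0.01, p_floor = 1e-16) {
  tailProbability(scoreDistribution(pwm_freqs, bg, bin), w, p_floor)
}

## per-window precomputation shared across motifs: base codes and cumulative
## background log2 conditionals for both alleles and both orientations
prepareWindow <- function(window_row, bg) {
  seqs <- list(
    ref_plus = window_row$ref_seq, alt_plus = window_row$alt_seq,
    ref_minus = revcompStr(window_row$ref_seq),
    alt_minus = revcompStr(window_row$alt_seq))
  lapply(seqs, function(s) {
    list(codes = dnaCodes(s),
         bgcum = c(0, cumsum(windowConditionalLog2(bg, s))))
  })
}

## best hit for one allele over both strands; offsets are 1-based site starts
## in plus-strand window coordinates. Ties: + strand first, then lowest offset.
bestAlleleHit <- function(prep_plus, prep_minus, logf, L, n, vpos1, dist) {
  scoreStrand <- function(prep, vpos) {
    off <- seq.int(max(1L, vpos - L + 1L), min(n - L + 1L, vpos))
    w <- numeric(length(off))
    for (j in seq_len(L)) {
      w <- w + logf[cbind(prep$codes[off + j - 1L], j)]
    }
    list(offsets = off, weights = w - (prep$bgcum[off + L] - prep$bgcum[off]))
  }
  sp <- scoreStrand(prep_plus, vpos1)
  sm <- scoreStrand(prep_minus, n + 1L - vpos1)
  # map minus-strand starts back to plus coordinates
  sm_orig <- n - (sm$offsets + L - 1L) + 1L
  offset <- c(sp$offsets, sm_orig)
  minus <- rep(c(FALSE, TRUE), c(length(sp$offsets), length(sm_orig)))
  weight <- c(sp$weights, sm$weights)
  ord <- order(-weight, minus, offset)
  i <- ord[1L]
  list(weight = weight[i], offset = offset[i] - 1L, # report 0-based
       strand = if (minus[i]) "-" else "+",
       p = tailProbability(dist, weight[i]))
}

#' Scan variant windows for allele-specific motif alterations
#'
#' For every (variant window, motif) combination, scores every site that
#' covers the variant base on both strands and both alleles, keeps the
#' maximum-weight hit per allele, and derives the allele contrast: absolute
#' weight difference, p-value ratio (larger / smaller, >= 1) and effect
#' call (`disrupt` when the reference allele binds better, `create` when
#' the alternate does).
#'
#' @param windows data.frame from [buildVariantWindows()].
#' @param motifs list of [PWMotif-class] objects.
#' @param bg a [MarkovBackground-class] (one consequence-set model; loop
#'   sets for per-set scanning).
#' @param pseudocount PWM pseudocount for [pwmFrequencies()].
#' @param bin score grid resolution for p-values.
#' @param cache optional environment reusing score distributions across
#'   calls (keyed by matrix id, background label, bin and pseudocount).
#' @return data.frame, one row per (variant, matrix): best-hit fields for
#'   each allele plus weight_diff, pval_ratio, effect.
#' @export
scanVariants <- function(windows, motifs, bg, pseudocount = 1, bin = 0.01,
                         cache = NULL) {
  if (!nrow(windows)) {
    return(emptyScanFrame())
  }
  preps <- lapply(seq_len(nrow(windows)),
                  function(i) prepareWindow(windows[i, ], bg))
  out <- vector("list", length(motifs))
  for (mi in seq_along(motifs)) {
    motif <- motifs[[mi]]
    L <- motifLength(motif)
    n <- nchar(windows$ref_seq[1L])
    if (L > n) {
      warning("motif ", motifId(motif), " (L=", L,
              ") longer than the scan window; skipped")
      next
    }
    f <- pwmFrequencies(motif, pseudocount)
    logf <- log2(f)
    key <- paste(motifId(motif), bgLabel(bg), bin, pseudocount, sep = "|")
    dist <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
      d <- scoreDistribution(f, bg, bin)
      if (!is.null(cache)) cache[[key]] <- d
      d
    }
    nw_all <- nchar(windows$ref_seq)
    nwin <- nrow(windows)
    rw <- rp <- aw <- ap <- numeric(nwin)
    ro <- ao <- integer(nwin)
    rs <- as_ <- character(nwin)
    for (wi in seq_len(nwin)) {
      vpos1 <- windows$variant_offset[wi] + 1L
      pr <- preps[[wi]]
      ref <- bestAlleleHit(pr$ref_plus, pr$ref_minus, logf, L, nw_all[wi],
                           vpos1, dist)
      alt <- bestAlleleHit(pr$alt_plus, pr$alt_minus, logf, L, nw_all[wi],
                           vpos1, dist)
      rw[wi] <- ref$weight; rp[wi] <- ref$p
      ro[wi] <- ref$offset; rs[wi] <- ref$strand
      aw[wi] <- alt$weight; ap[wi] <- alt$p
      ao[wi] <- alt$offset; as_[wi] <- alt$strand
    }
    out[[mi]] <- data.frame(
      variant_id = windows$variant_id, matrix_id = motifId(motif),
      tf_name = tfName(motif),
      ref_weight = rw, ref_pvalue = rp, ref_offset = ro, ref_strand = rs,
      alt_weight = aw, alt_pvalue = ap, alt_offset = ao, alt_strand = as_,
      weight_diff = abs(rw - aw),
      pval_ratio = pmax(rp, ap) / pmin(rp, ap),
      effect = ifelse(rw > aw, "disrupt", ifelse(aw > rw, "create", "none")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) emptyScanFrame() else { rownames(res) <- NULL; res }
}

emptyScanFrame <- function() {
  data.frame(variant_id = character(), matrix_id = character(),
             tf_name = character(), ref_weight = numeric(),
             ref_pvalue = numeric(), ref_offset = integer(),
             ref_strand = character(), alt_weight = numeric(),
             alt_pvalue = numeric(), alt_offset = integer(),
             alt_strand = character(), weight_diff = numeric(),
             pval_ratio = numeric(), effect = character(),
             stringsAsFactors = FALSE)
}

#' Scan a single variant window against one motif
#'
#' @param motif a [PWMotif-class].
#' @param bg a [MarkovBackground-class].
#' @param window one-row data.frame from [buildVariantWindows()].
#' @param ... passed to [scanVariants()].
#' @return one-row scan data.frame.
#' @export
scanVariant <- function(motif, bg, window, ...) {
  scanVariants(window, list(motif), bg, ...)
}

#' Retention filters for allele-specific scan results
#'
#' Keeps results with best-site weight > `weight_min`, weight difference
#' > `weight_diff_min`, best-site p-value < `pvalue_max` and p-value
#' ratio > `ratio_min`; all comparisons strict.
#'
#' @param results data.frame from [scanVariants()].
#' @param weight_min,weight_diff_min,pvalue_max,ratio_min thresholds
#'   (defaults 1, 1, 1e-3, 10).
#' @return the retained subset.
#' @export
applyScanFilters <- function(results, weight_min = 1, weight_diff_min = 1,
                             pvalue_max = 1e-3, ratio_min = 10) {
  keep <- pmax(results$ref_weight, results$alt_weight) > weight_min &
    results$weight_diff > weight_diff_min &
    pmin(results$ref_pvalue, results$alt_pvalue) < pvalue_max &
    results$pval_ratio > ratio_min
  results[keep, , drop = FALSE]
}
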