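## ---- Markov background estimation -----------------------------------------

## context/next counts of one ACGT run, counted circularly (wrap-around).
## Circular counting makes the context marginal equal the k-mer frequency
## exactly, which in turn makes the estimated model exactly strand-symmetric
## (see methods vignette).
countRun <- function(codes, k, counts) {
  n <- length(codes)
  if (n < k + 1L) return(counts)
  ext <- c(codes, codes[seq_len(k)])
  idx <- rep(0L, n)
  if (k > 0) {
    for (j in seq_len(k)) {
      idx <- idx * 4L + (ext[seq_len(n) + j - 1L] - 1L)
    }
  }
  nxt <- ext[seq_len(n) + k]
  tab <- table(factor(idx + 1L, levels = seq_len(4^k)),
               factor(nxt, levels = 1:4))
  counts + as.matrix(unclass(tab))
}

#' Estimate an order-k Markov background model
#'
#' Counts (context, next base) transitions over the training sequences and,
#' by default, their reverse complements, with wrap-around (circular)
#' counting within each uninterrupted A/C/G/T run. Non-ACGT characters and
#' their contexts are skipped. The stationary distribution is proportional
#' to the pseudocount-augmented context totals, which makes the model
#' assign exactly equal probability to a sequence and its reverse
#' complement.
#'
#' @param sequences character vector of training sequences.
#' @param order model order k >= 0 (2 captures CpG depletion).
#' @param pseudocount added to every (context, base) cell (default 1).
#' @param revcomp augment training with reverse complements (default TRUE;
#'   required for strand-symmetric scanning).
#' @param label set label stored on the model.
#' @return a [MarkovBackground-class].
#' @export
estimateMarkov <- function(sequences, order = 2, pseudocount = 1,
                           revcomp = TRUE, label = "global") {
  stopifnot(order >= 0, length(sequences) > 0, pseudocount >= 0)
  order <- as.integer(order)
  seqs <- toupper(sequences)
  if (revcomp) seqs <- c(seqs, revcompStr(seqs))
  counts <- matrix(0, nrow = 4^order, ncol = 4)
  usable <- FALSE
  for (s in seqs) {
    runs <- strsplit(s, "[^ACGT]+")[[1]]
    runs <- runs[nchar(runs) >= order + 1L]
    for (run in runs) {
      counts <- countRun(dnaCodes(run), order, counts)
      usable <- TRUE
    }
  }
  if (!usable) {
    stop("model order (", order, ") is larger than every training sequence")
  }
  counts <- counts + pseudocount
  ctx <- allKmers(order)
  rowtot <- rowSums(counts)
  tr <- counts / rowtot
  # contexts never seen and with zero pseudocount: uniform row, zero weight
  dead <- rowtot == 0
  if (any(dead)) tr[dead, ] <- 0.25
  dimnames(tr) <- list(ctx, DNA_BASES)
  st <- if (sum(rowtot) > 0) rowtot / sum(rowtot) else
    rep(1 / length(rowtot), length(rowtot))
  names(st) <- ctx
  new("MarkovBackground", order = order, transitions = tr,
      stationary = st, label = label, pseudocount = pseudocount)
}

## conditional next-base distribution given a (possibly short) context.
## Shorter contexts marginalize the unknown prefix with the stationary
## distribution over full contexts.
contextConditional <- function(bg, ctx) {
  k <- bg@order
  if (k == 0) return(bg@transitions[1L, ])
  if (nchar(ctx) >= k) {
    use <- substr(ctx, nchar(ctx) - k + 1L, nchar(ctx))
    return(bg@transitions[use, ])
  }
  rows <- rownames(bg@transitions)
  sel <- if (nchar(ctx) == 0) rep(TRUE, length(rows)) else
    endsWith(rows, ctx)
  w <- bg@stationary[sel]
  if (sum(w) == 0) w <- rep(1, sum(sel))
  drop(crossprod(w / sum(w), bg@transitions[sel, , drop = FALSE]))
}

#' Log2 probability of a sequence under a background model
#'
#' `log2 stationary(first k-mer) + sum of log2 transition probabilities`.
#' With pseudocount 0, an unseen transition yields `-Inf`.
#'
#' @param bg a [MarkovBackground-class].
#' @param seq DNA string with length > order.
#' @return log2 probability.
#' @export
sequenceLogProb <- function(bg, seq) {
  k <- bg@order
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n <= k) stop("sequence must be longer than the model order")
  codes <- dnaCodes(seq)
  if (any(is.na(codes))) stop("sequence contains non-ACGT characters")
  lp <- 0
  if (k > 0) {
    first <- substr(seq, 1L, k)
    lp <- lp + log2(bg@stationary[[first]])
  }
  for (i in (k + 1L):n) {
    row <- if (k == 0) 1L else
      match(substr(seq, i - k, i - 1L), rownames(bg@transitions))
    lp <- lp + log2(bg@transitions[row, codes[i]])
  }
  unname(lp)
}

## per-position log2 P(base_i | preceding context within the window) for a
## whole window; early positions (< k preceding bases) use the marginalized
## conditional. Returns a numeric vector of length nchar(window).
windowConditionalLog2 <- function(bg, window) {
  k <- bg@order
  n <- nchar(window)
  codes <- dnaCodes(window)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pr <- if (k == 0) bg@transitions[1L, ] else if (i - 1L >= k) {
      bg@transitions[substr(window, i - k, i - 1L), ]
    } else contextConditional(bg, substr(window, 1L, i - 1L))
    out[i] <- log2(pr[[codes[i]]])
  }
  out
}

## ---- Variant flanking windows ---------------------------------------------

#' Build ref/alt flanking windows around variants
#'
#' Extracts `flank` bases on each side of every variant (window length
#' `2 * flank + 1` when not truncated by a chromosome end) and substitutes
#' the alternate allele at the variant position for the alt window.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param variants data.frame with variant_id, chrom, pos, ref, alt
#'   (single bases).
#' @param flank bases per side (default 30).
#' @return data.frame (variant_id, chrom, pos, ref_seq, alt_seq, flank,
#'   variant_offset) with `variant_offset` the 0-based index of the
#'   variant base within the window.
#' @export
buildVariantWindows <- function(genome, variants, flank = 30) {
  stopifnotCols(variants, c("variant_id", "chrom", "pos", "ref", "alt"),
                "variants")
  if (!nrow(variants)) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref_seq = character(),
                      alt_seq = character(), flank = integer(),
                      variant_offset = integer(), stringsAsFactors = FALSE))
  }
  bad <- !toupper(variants$ref) %in% DNA_BASES |
    !toupper(variants$alt) %in% DNA_BASES |
    toupper(variants$ref) == toupper(variants$alt) | variants$pos < 1
  if (any(bad)) {
    stop("invalid SNV allele/position for: ",
         paste(variants$variant_id[bad], collapse = ", "),
         " (single A/C/G/T alleles with ref != alt required)")
  }
  n <- nrow(variants)
  ref_seq <- alt_seq <- character(n)
  offs <- integer(n)
  truncated <- character(0)
  for (i in seq_len(n)) {
    chrom <- variants$chrom[i]
    pos <- variants$pos[i]
    len <- nchar(chromSeq(genome, chrom))
    start <- max(1L, pos - flank)
    end <- min(len, pos + flank)
    if (start != pos - flank || end != pos + flank) {
      truncated <- c(truncated, variants$variant_id[i])
    }
    w <- fetchSequence(genome, chrom, start, end)
    off <- pos - start
    gbase <- substr(w, off + 1L, off + 1L)
    if (gbase != toupper(variants$ref[i])) {
      stop("reference mismatch for ", variants$variant_id[i], ": genome has ",
           gbase, ", variant declares ", variants$ref[i])
    }
    a <- w
    substr(a, off + 1L, off + 1L) <- toupper(variants$alt[i])
    ref_seq[i] <- w
    alt_seq[i] <- a
    offs[i] <- off
  }
  if (length(truncated)) {
    warning("window truncated at a chromosome end for: ",
            paste(truncated, collapse = ", "))
  }
  data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
             pos = variants$pos, ref_seq = ref_seq, alt_seq = alt_seq,
             flank = flank, variant_offset = offs, stringsAsFactors = FALSE)
}
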