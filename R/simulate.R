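#' Simulation configuration with study-scale defaults
#'
#' Defaults describe the desk-scale study conditions: a 2 Mb two-chromosome
#' genome with CpG depletion, 60 genes, 20 association loci of 15 variants,
#' 12 motifs of 8-14 bp with 10-16 bits of information, 10 planted causal
#' loci of which 60 percent colocalize with an eQTL, 4 planted
#' variant-TF-eGene triples, 300 bp peaks, and a 2000-variant matched
#' control pool.
#'
#' @param seed integer seed driving every random choice.
#' @param ... overrides for any default listed below.
#' @return a named list of simulation parameters.
#' @export
simulationConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chrom = 2L,
    chrom_length = 1000000L,
    gc = 0.42,
    cpg_depletion = 0.25,
    n_genes = 60L,
    n_loci = 20L,
    locus_size = 15L,
    n_motifs = 12L,
    motif_length_range = c(8L, 14L),
    motif_ic_range = c(10, 16),
    n_planted_causal = 10L,
    planted_coloc_fraction = 0.6,
    planted_triple_count = 4L,
    binding_per_motif = 2L,
    create_fraction = 0.25,
    n_decoy_peaks = 40L,
    decoys_per_peak = 3L,
    peak_width = 300L,
    pool_size = 2000L,
    segment_width = 2000L,
    active_state_fraction = 0.5,
    causal_pics = 0.6,
    eqtl_pics = 0.6,
    biosamples = c("Brain Dorsolateral Prefrontal Cortex",
                   "Brain Hippocampus Middle", "Astrocytes"),
    tissues = c("Brain_Cortex", "Brain_Cerebellar_Hemisphere",
                "Brain_Hippocampus", "Brain_Putamen_basal_ganglia",
                "Liver", "Whole_Blood"),
    triple_groups = c("cortex", "hippocampus")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_planted_causal <= cfg$n_loci,
            cfg$planted_triple_count <= cfg$n_motifs)
  cfg
}

## ---- genome + genes -------------------------------------------------------

#' Simulate a CpG-depleted genome and non-overlapping gene annotation
#'
#' Bases are drawn iid at the configured GC content, then the G of each CpG
#' dinucleotide is resampled with probability `1 - cpg_depletion`, leaving
#' an observed/expected CpG ratio close to `cpg_depletion`. Uses the
#' current RNG state (seeded by [simulateRegulatoryData()]).
#'
#' @param config from [simulationConfig()].
#' @return list with `genome` (named character vector) and `genes`
#'   (data.frame gene_id, gene_name, chrom, start, end, strand, tss).
#' @export
simulateGenomeAndGenes <- function(config) {
  p <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
         (1 - config$gc) / 2)
  genome <- setNames(vector("character", config$n_chrom),
                     paste0("chr", seq_len(config$n_chrom)))
  # CpG thinning: keep each CpG with probability t and replace the G of
  # the others with A/T (never C, so no new CpGs arise). Removing G mass
  # also shrinks the expected-count denominator, so the keep rate t that
  # yields a final observed/expected ratio d is t = d(1-pC)/(1 - d*pC).
  pC <- config$gc / 2
  d <- config$cpg_depletion
  t_keep <- d * (1 - pC) / (1 - d * pC)
  for (ci in seq_len(config$n_chrom)) {
    n <- config$chrom_length
    codes <- sample.int(4L, n, replace = TRUE, prob = p)
    cg <- which(codes[-n] == 2L & codes[-1L] == 3L)
    kill <- cg[runif(length(cg)) > t_keep]
    if (length(kill)) {
      codes[kill + 1L] <- sample(c(1L, 4L), length(kill), replace = TRUE,
                                 prob = p[c(1, 4)])
    }
    genome[ci] <- paste(DNA_BASES[codes], collapse = "")
  }
  per <- ceiling(config$n_genes / config$n_chrom)
  rows <- list()
  gid <- 0L
  for (ci in seq_len(config$n_chrom)) {
    ngenes <- min(per, config$n_genes - gid)
    slot <- floor(config$chrom_length / (ngenes + 1))
    if (slot < 4000) stop("genes unplaceable at this density")
    for (g in seq_len(ngenes)) {
      gid <- gid + 1L
      len <- sample(2000:min(15000, slot - 1000), 1L)
      start <- (g - 1L) * slot + sample(500:(slot - len - 500), 1L)
      strand <- sample(c("+", "-"), 1L)
      rows[[gid]] <- data.frame(
        gene_id = sprintf("G%03d", gid), gene_name = sprintf("GENE%03d", gid),
        chrom = paste0("chr", ci), start = start, end = start + len - 1L,
        strand = strand, tss = if (strand == "+") start else start + len - 1L,
        stringsAsFactors = FALSE)
    }
  }
  list(genome = genome, genes = do.call(rbind, rows))
}

## sample motif count matrices with a target information content
simulateMotifs <- function(config) {
  lapply(seq_len(config$n_motifs), function(i) {
    L <- sample(seq(config$motif_length_range[1], config$motif_length_range[2]),
                1L)
    target <- runif(1, config$motif_ic_range[1], config$motif_ic_range[2])
    # sharp column (97, 2, 1, 0 counts) ~1.78 bits, soft column ~0.29 bits;
    # zero minor counts are typical of curated matrices
    n_sharp <- max(1L, min(L, round((target - 0.29 * L) / (1.78 - 0.29))))
    sharp <- sample(seq_len(L), n_sharp)
    cnt <- sapply(seq_len(L), function(j) {
      cons <- sample.int(4L, 1L)
      v <- rep(0, 4)
      if (j %in% sharp) {
        v[cons] <- 97
        v[-cons] <- sample(c(2, 1, 0))
      } else {
        v[cons] <- 55
        v[-cons] <- 15
      }
      v
    })
    rownames(cnt) <- DNA_BASES
    PWMotif(sprintf("M%02d", i), sprintf("TF%02d", i), cnt, "simulated")
  })
}

## ---- peaks, motif instances, variants -------------------------------------

#' Plant motif instances in peaks and derive binding-alteration variants
#'
#' Every peak carries one embedded instance of its motif, written into the
#' genome. Planted binding-alteration variants sit on a high-information
#' column of the embedded instance: for a `disrupt` variant the genome
#' carries the consensus base (ref) and the alternate allele is the
#' minimum-frequency base; a `create` variant is the mirror image. Decoy
#' variants are placed inside peaks but outside the instance.
#'
#' @param config from [simulationConfig()].
#' @param genome named character vector (modified copy is returned).
#' @param motifs list of [PWMotif-class].
#' @return list: `genome` (with instances written in), `peaks` (BED-style
#'   data.frame), `binding` (truth data.frame variant_id, matrix_id,
#'   tf_name, effect), `binding_variants` and `decoy_variants`
#'   (data.frames with chrom/pos/ref/alt).
#' @export
plantMotifsAndVariants <- function(config, genome, motifs) {
  n_binding <- config$n_motifs * config$binding_per_motif +
    config$planted_triple_count
  motif_for_binding <- c(rep(seq_len(config$n_motifs),
                             config$binding_per_motif),
                         seq_len(config$planted_triple_count))
  n_peaks <- n_binding + config$n_decoy_peaks
  decoy_motif <- sample.int(config$n_motifs, config$n_decoy_peaks,
                            replace = TRUE)
  peak_motif <- c(motif_for_binding, decoy_motif)
  chroms <- names(genome)
  used <- lapply(chroms, function(x) integer(0))
  names(used) <- chroms
  w <- config$peak_width
  peaks <- data.frame(chrom = character(n_peaks), start = integer(n_peaks),
                      end = integer(n_peaks), name = character(n_peaks),
                      stringsAsFactors = FALSE)
  inst_start <- integer(n_peaks)
  for (i in seq_len(n_peaks)) {
    placed <- FALSE
    for (try in 1:200) {
      ch <- sample(chroms, 1L)
      s0 <- sample.int(nchar(genome[[ch]]) - w - 100L, 1L) # 0-based start
      if (!any(abs(used[[ch]] - s0) < w + 50L)) {
        used[[ch]] <- c(used[[ch]], s0)
        peaks$chrom[i] <- ch; peaks$start[i] <- s0
        peaks$end[i] <- s0 + w; peaks$name[i] <- sprintf("peak%03d", i)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place peak ", i, " without overlap")
  }
  binding <- list()
  binding_variants <- list()
  decoy_variants <- list()
  vid <- 0L
  for (i in seq_len(n_peaks)) {
    m <- motifs[[peak_motif[i]]]
    L <- motifLength(m)
    f <- sweep(m@counts, 2L, colSums(m@counts), "/")
    cons <- apply(m@counts, 2L, which.max)
    worst <- apply(m@counts, 2L, which.min)
    # instance near the peak centre (1-based genome coordinates)
    istart <- peaks$start[i] + floor((config$peak_width - L) / 2) + 1L
    inst_start[i] <- istart
    instance <- cons
    is_binding <- i <= n_binding
    effect <- NA_character_
    col <- NA_integer_
    if (is_binding) {
      sharp_cols <- which(f[cbind(cons, seq_len(L))] -
                            f[cbind(worst, seq_len(L))] > 0.7)
      if (!length(sharp_cols)) sharp_cols <- seq_len(L)
      col <- sample(rep(sharp_cols, 2L), 1L)
      effect <- if (runif(1) < config$create_fraction) "create" else "disrupt"
      if (effect == "create") instance[col] <- worst[col]
    }
    ch <- peaks$chrom[i]
    s <- genome[[ch]]
    substr(s, istart, istart + L - 1L) <- paste(DNA_BASES[instance],
                                                collapse = "")
    genome[[ch]] <- s
    if (is_binding) {
      vid <- vid + 1L
      pos <- istart + col - 1L
      ref <- DNA_BASES[instance[col]]
      alt <- DNA_BASES[if (effect == "disrupt") worst[col] else cons[col]]
      id <- sprintf("rsB%04d", vid)
      binding[[vid]] <- data.frame(
        variant_id = id, matrix_id = motifId(m), tf_name = tfName(m),
        effect = effect, stringsAsFactors = FALSE)
      binding_variants[[vid]] <- data.frame(
        variant_id = id, chrom = ch, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    } else {
      for (d in seq_len(config$decoys_per_peak)) {
        # decoy inside the peak but clear of the embedded instance
        for (try in 1:50) {
          pos <- peaks$start[i] + sample.int(config$peak_width, 1L)
          if (pos < istart - 1L || pos > istart + L) break
        }
        ref <- substr(genome[[ch]], pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        decoy_variants[[length(decoy_variants) + 1L]] <- data.frame(
          variant_id = sprintf("rsD%04d", length(decoy_variants) + 1L),
          chrom = ch, pos = pos, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(genome = genome, peaks = peaks,
       binding = do.call(rbind, binding),
       binding_variants = do.call(rbind, binding_variants),
       decoy_variants = do.call(rbind, decoy_variants))
}

## ---- loci, association, PICS ----------------------------------------------

#' Simulate loci, the association table, LD and the GWAS PICS table
#'
#' Planted causal loci put the causal variant at the index position with a
#' dominant PICS probability; non-causal loci spread probability so that no
#' member exceeds 0.10. Per-locus probabilities sum to 1.
#'
#' @param config from [simulationConfig()].
#' @param genome named character vector (for reference alleles).
#' @param in_peak_variants data.frame of variants that must be locus
#'   members (planted binding + decoy variants).
#' @return list with `variants`, `associations`, `ld`, `gwas_pics`,
#'   `causal_ids`.
#' @export
simulateLociAndPics <- function(config, genome, in_peak_variants) {
  n_slots <- config$n_loci * config$locus_size
  n_extra <- n_slots - config$n_loci - nrow(in_peak_variants)
  if (n_extra < 0) stop("locus capacity too small for the in-peak variants")
  chroms <- names(genome)
  randomVariants <- function(n, prefix) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      ch <- sample(chroms, 1L)
      pos <- sample.int(nchar(genome[[ch]]) - 100L, 1L) + 50L
      ref <- substr(genome[[ch]], pos, pos)
      out[[i]] <- data.frame(
        variant_id = sprintf("%s%05d", prefix, i), chrom = ch, pos = pos,
        ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1L),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  index_vars <- randomVariants(config$n_loci, "rsI")
  extra_vars <- randomVariants(n_extra, "rsX")
  member_pool <- rbind(in_peak_variants, extra_vars)
  member_pool <- member_pool[sample.int(nrow(member_pool)), , drop = FALSE]
  per_locus <- config$locus_size - 1L
  rows_assoc <- rows_ld <- rows_pics <- rows_var <- list()
  for (li in seq_len(config$n_loci)) {
    idx <- index_vars[li, ]
    members <- member_pool[((li - 1L) * per_locus + 1L):(li * per_locus), ]
    logp <- runif(1, 8.5, 25)
    rows_assoc[[li]] <- data.frame(
      variant_id = idx$variant_id, chrom = idx$chrom, pos = idx$pos,
      p_value = 10^(-logp), is_index = TRUE, stringsAsFactors = FALSE)
    r2 <- round(runif(per_locus, 0.5, 0.99), 3)
    rows_ld[[li]] <- data.frame(
      variant_a = idx$variant_id, variant_b = members$variant_id, r2 = r2,
      stringsAsFactors = FALSE)
    planted <- li <= config$n_planted_causal
    probs <- if (planted) {
      c(config$causal_pics,
        rep((1 - config$causal_pics) / per_locus, per_locus))
    } else {
      rep(1 / config$locus_size, config$locus_size)
    }
    rows_pics[[li]] <- data.frame(
      variant_id = c(idx$variant_id, members$variant_id),
      locus_id = idx$variant_id, pics_prob = probs, source = "gwas",
      tissue = "", egene = "", stringsAsFactors = FALSE)
    rows_var[[li]] <- cbind(rbind(idx, members),
                            locus_id = idx$variant_id)
  }
  # non-significant index records exercise the significance filter
  nonsig <- randomVariants(3L, "rsN")
  rows_assoc[[config$n_loci + 1L]] <- data.frame(
    variant_id = nonsig$variant_id, chrom = nonsig$chrom, pos = nonsig$pos,
    p_value = 10^(-runif(3, 5, 7)), is_index = TRUE, stringsAsFactors = FALSE)
  list(variants = do.call(rbind, rows_var),
       associations = do.call(rbind, rows_assoc),
       ld = do.call(rbind, rows_ld),
       gwas_pics = do.call(rbind, rows_pics),
       causal_ids = index_vars$variant_id[seq_len(config$n_planted_causal)])
}

## position-derived consequence terms; in-peak variants also get a
## regulatory term so set (c) is populated
consequenceTerms <- function(variants, genes, peaks) {
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  pconv <- bedToOneBased(peaks$start, peaks$end)
  pr <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(pconv$start, pconv$end))
  in_gene <- GenomicRanges::countOverlaps(vr, gr) > 0
  in_peak <- GenomicRanges::countOverlaps(vr, pr) > 0
  terms <- ifelse(in_gene, "intron_variant", "intergenic_variant")
  nc <- runif(nrow(variants)) < 0.3
  terms[nc] <- paste0(terms[nc], ",non_coding_transcript_variant")
  reg <- in_peak & runif(nrow(variants)) < 0.5
  terms[reg] <- paste0(terms[reg], ",regulatory_region_variant")
  terms
}

## ---- eQTL, expression, TF targets, chromatin ------------------------------

#' Simulate eQTL PICS, TPM matrix, TF-target records and chromatin states
#'
#' Planted colocalizing variants receive an eQTL PICS probability >= the
#' configured value for the nearest gene in a brain tissue; planted triples
#' add a tissue-matched TF-target record and set the TF's TPM >= 2; peaks
#' of planted binding variants are covered by active chromatin in the
#' first brain biosample. Distractor eQTLs are drawn on the control pool
#' and never coincide with GWAS-significant variants.
#'
#' @param config from [simulationConfig()].
#' @param parts list carrying genes, variants, pool, binding, causal_ids,
#'   peaks (as assembled by [simulateRegulatoryData()]).
#' @return list with `eqtl_pics`, `tpm`, `tftarget`, `chromhmm`, and truth
#'   components `coloc` and `triples`.
#' @export
simulateEqtlExpressionTargets <- function(config, parts) {
  genes <- parts$genes
  tmap <- defaultTissueMap()
  nearestGene <- function(chrom, pos) {
    g <- genes[genes$chrom == chrom, ]
    g$gene_id[which.min(abs(g$tss - pos))]
  }
  brain_groups <- tmap$group[tmap$eqtl_tissue %in% config$tissues]
  ## colocalizing causal variants
  n_coloc <- round(config$n_planted_causal * config$planted_coloc_fraction)
  coloc_ids <- parts$causal_ids[seq_len(min(n_coloc,
                                            length(parts$causal_ids)))]
  vv <- parts$variants
  rows_eqtl <- list()
  coloc_rows <- list()
  for (id in coloc_ids) {
    v <- vv[vv$variant_id == id, ][1, ]
    grp <- sample(brain_groups, 1L)
    tis <- tmap$eqtl_tissue[tmap$group == grp]
    eg <- nearestGene(v$chrom, v$pos)
    rows_eqtl[[length(rows_eqtl) + 1L]] <- data.frame(
      variant_id = id, locus_id = id, pics_prob = config$eqtl_pics,
      source = "eqtl", tissue = tis, egene = eg, stringsAsFactors = FALSE)
    coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
      variant_id = id, egene = eg, tissue = tis, stringsAsFactors = FALSE)
  }
  ## mechanistic triples on the first planted binding variant of each of
  ## the first `planted_triple_count` motifs (the extra per-motif plant)
  bind <- parts$binding
  n_binding_regular <- config$n_motifs * config$binding_per_motif
  triple_rows <- list()
  tftarget <- list()
  triple_tfs <- character(0)
  triple_egenes <- character(0)
  for (t in seq_len(config$planted_triple_count)) {
    b <- bind[n_binding_regular + t, ]
    v <- vv[vv$variant_id == b$variant_id, ][1, ]
    grp <- sample(config$triple_groups, 1L)
    tis_e <- tmap$eqtl_tissue[tmap$group == grp]
    tis_t <- tmap$tftarget_tissue[tmap$group == grp]
    eg <- nearestGene(v$chrom, v$pos)
    rows_eqtl[[length(rows_eqtl) + 1L]] <- data.frame(
      variant_id = b$variant_id, locus_id = b$variant_id,
      pics_prob = config$eqtl_pics, source = "eqtl", tissue = tis_e,
      egene = eg, stringsAsFactors = FALSE)
    tftarget[[length(tftarget) + 1L]] <- data.frame(
      tf_name = b$tf_name, target_gene = eg, tissue = tis_t,
      stringsAsFactors = FALSE)
    triple_rows[[t]] <- data.frame(
      variant_id = b$variant_id, tf_name = b$tf_name, egene = eg,
      eqtl_tissue = tis_e, tftarget_tissue = tis_t, stringsAsFactors = FALSE)
    triple_tfs <- c(triple_tfs, b$tf_name)
    triple_egenes <- c(triple_egenes, eg)
  }
  ## distractor eQTLs on the pool (never GWAS-significant variants)
  pool <- parts$pool
  n_distr <- min(30L, nrow(pool))
  dsel <- sample.int(nrow(pool), n_distr)
  for (i in dsel) {
    rows_eqtl[[length(rows_eqtl) + 1L]] <- data.frame(
      variant_id = pool$variant_id[i], locus_id = pool$variant_id[i],
      pics_prob = round(runif(1, 0.02, 0.5), 3), source = "eqtl",
      tissue = sample(config$tissues, 1L),
      egene = sample(setdiff(genes$gene_id, triple_egenes), 1L),
      stringsAsFactors = FALSE)
  }
  ## distractor TF-target rows avoid planted TFs and eGenes
  all_tfs <- unique(vapply(parts$motifs, tfName, character(1)))
  free_tfs <- setdiff(all_tfs, triple_tfs)
  for (i in seq_len(20L)) {
    tftarget[[length(tftarget) + 1L]] <- data.frame(
      tf_name = sample(free_tfs, 1L),
      target_gene = sample(setdiff(genes$gene_id, triple_egenes), 1L),
      tissue = sample(tmap$tftarget_tissue, 1L), stringsAsFactors = FALSE)
  }
  ## expression: genes and TFs x tissues, lognormal TPM
  tfs <- sort(unique(all_tfs))
  rn <- c(genes$gene_id, tfs)
  tpm <- matrix(round(2^rnorm(length(rn) * length(config$tissues), 2, 1.5), 3),
                nrow = length(rn),
                dimnames = list(rn, config$tissues))
  if (length(triple_tfs)) {
    tpm[triple_tfs, ] <- pmax(tpm[triple_tfs, , drop = FALSE], 5)
  }
  low_tfs <- sample(setdiff(tfs, triple_tfs), 2L)
  tpm[low_tfs, ] <- round(matrix(runif(2 * ncol(tpm), 0, 1.5),
                                 nrow = 2), 3)
  ## chromatin states: tiled segments per biosample; planted binding
  ## variants forced into an active state in the first biosample
  act <- activeChromhmmStates()
  inact <- setdiff(chromhmmStates(), act)
  seg_rows <- list()
  for (bs in config$biosamples) {
    for (ch in names(parts$genome)) {
      len <- nchar(parts$genome[[ch]])
      starts <- seq(0L, len - 1L, by = config$segment_width)
      ends <- pmin(starts + config$segment_width, len)
      active <- runif(length(starts)) < config$active_state_fraction
      states <- ifelse(active, sample(act, length(starts), replace = TRUE),
                       sample(inact, length(starts), replace = TRUE))
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chrom = ch, start = starts, end = ends, name = states,
        biosample = bs, stringsAsFactors = FALSE)
    }
  }
  chromhmm <- do.call(rbind, seg_rows)
  bvar <- vv[vv$variant_id %in% bind$variant_id, , drop = FALSE]
  first_bs <- config$biosamples[1]
  for (i in seq_len(nrow(bvar))) {
    sel <- chromhmm$biosample == first_bs &
      chromhmm$chrom == bvar$chrom[i] &
      chromhmm$start < bvar$pos[i] & chromhmm$end >= bvar$pos[i]
    chromhmm$name[sel] <- sample(act, sum(sel), replace = TRUE)
  }
  emptyTriples <- data.frame(variant_id = character(),
                             tf_name = character(), egene = character(),
                             eqtl_tissue = character(),
                             tftarget_tissue = character(),
                             stringsAsFactors = FALSE)
  coloc <- do.call(rbind, coloc_rows)
  if (is.null(coloc)) {
    coloc <- data.frame(variant_id = character(), egene = character(),
                        tissue = character(), stringsAsFactors = FALSE)
  }
  triples <- do.call(rbind, triple_rows)
  if (is.null(triples)) triples <- emptyTriples
  list(eqtl_pics = do.call(rbind, rows_eqtl), tpm = tpm,
       tftarget = unique(do.call(rbind, tftarget)), chromhmm = chromhmm,
       coloc = coloc, triples = triples)
}

## ---- orchestrator ---------------------------------------------------------

#' Simulate a complete self-consistent regulatory-variation dataset
#'
#' Generates every input the analysis pipeline consumes plus a ground-truth
#' manifest of the planted signal. Fully deterministic under
#' `config$seed`.
#'
#' @param config from [simulationConfig()].
#' @return list with genome, genes, motifs, peaks, variants (locus
#'   members), pool (matched-control pool), associations, ld, gwas_pics,
#'   eqtl_pics, chromhmm, tpm, tftarget, tissue_map, config, and `truth`
#'   (causal ids, binding alterations, coloc pairs, evidence triples).
#' @export
simulateRegulatoryData <- function(config = simulationConfig()) {
  set.seed(config$seed)
  gg <- simulateGenomeAndGenes(config)
  motifs <- simulateMotifs(config)
  pm <- plantMotifsAndVariants(config, gg$genome, motifs)
  in_peak <- rbind(pm$binding_variants, pm$decoy_variants)
  lp <- simulateLociAndPics(config, pm$genome, in_peak)
  ## matched-control pool; avoids peak footprints so that pool variants
  ## cannot fall on a planted instance (at this compressed genome scale a
  ## chance collision would contaminate the control null, which cannot
  ## happen at the density of real data)
  chroms <- names(pm$genome)
  inPeak <- function(ch, pos) {
    sel <- pm$peaks$chrom == ch
    any(pos > pm$peaks$start[sel] & pos <= pm$peaks$end[sel])
  }
  pool <- do.call(rbind, lapply(seq_len(config$pool_size), function(i) {
    repeat {
      ch <- sample(chroms, 1L)
      pos <- sample.int(nchar(pm$genome[[ch]]) - 100L, 1L) + 50L
      if (!inPeak(ch, pos)) break
    }
    ref <- substr(pm$genome[[ch]], pos, pos)
    data.frame(variant_id = sprintf("rsP%05d", i), chrom = ch, pos = pos,
               ref = ref, alt = sample(setdiff(DNA_BASES, ref), 1L),
               stringsAsFactors = FALSE)
  }))
  variants <- lp$variants
  variants$consequence_terms <- consequenceTerms(variants, gg$genes, pm$peaks)
  pool$consequence_terms <- consequenceTerms(pool, gg$genes, pm$peaks)
  variants$allele_freq <- round(runif(nrow(variants), 0.05, 0.5), 3)
  cadd <- round(runif(nrow(variants), 0, 14), 2)
  high <- runif(nrow(variants)) < 0.05
  cadd[high] <- round(runif(sum(high), 15, 30), 2)
  variants$cadd_phred <- cadd
  binding <- pm$binding
  if (is.null(binding)) {
    binding <- data.frame(variant_id = character(), matrix_id = character(),
                          tf_name = character(), effect = character(),
                          stringsAsFactors = FALSE)
  }
  parts <- list(genome = pm$genome, genes = gg$genes, variants = variants,
                pool = pool, binding = binding, motifs = motifs,
                causal_ids = lp$causal_ids, peaks = pm$peaks)
  ee <- simulateEqtlExpressionTargets(config, parts)
  out <- list(genome = pm$genome, genes = gg$genes, motifs = motifs,
              peaks = pm$peaks, variants = variants, pool = pool,
              associations = lp$associations, ld = lp$ld,
              gwas_pics = lp$gwas_pics, eqtl_pics = ee$eqtl_pics,
              chromhmm = ee$chromhmm, tpm = ee$tpm, tftarget = ee$tftarget,
              tissue_map = defaultTissueMap(), config = config,
              truth = list(causal = lp$causal_ids, binding = binding,
                           coloc = ee$coloc, triples = ee$triples))
  for (nm in names(out)) {
    if (is.data.frame(out[[nm]])) rownames(out[[nm]]) <- NULL
  }
  out$truth <- lapply(out$truth, function(x) {
    if (is.data.frame(x)) rownames(x) <- NULL
    x
  })
  out
}

## ---- file round trip ------------------------------------------------------

#' Write a simulated dataset to standard-format files
#'
#' Emits genome.fa, genes.tsv, variants.tsv, pool.tsv, associations.tsv,
#' ld.tsv, gwas_pics.tsv, eqtl_pics.tsv, peaks.bed, one
#' chromhmm_<biosample>.bed per biosample, motifs.jaspar, tpm.gct,
#' tftarget.tsv, tissue_map.tsv and truth.json.
#'
#' @param sim from [simulateRegulatoryData()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(sim$genes, "genes.tsv")
  tsv(sim$variants, "variants.tsv")
  tsv(sim$pool, "pool.tsv")
  tsv(sim$associations, "associations.tsv")
  tsv(sim$ld, "ld.tsv")
  tsv(sim$gwas_pics, "gwas_pics.tsv")
  tsv(sim$eqtl_pics, "eqtl_pics.tsv")
  tsv(sim$tftarget, "tftarget.tsv")
  tsv(sim$tissue_map, "tissue_map.tsv")
  writeBed(sim$peaks, file.path(dir, "peaks.bed"))
  for (bs in unique(sim$chromhmm$biosample)) {
    writeBed(sim$chromhmm[sim$chromhmm$biosample == bs, ],
             file.path(dir, paste0("chromhmm_", gsub("[^A-Za-z0-9]+", "_", bs),
                                   ".bed")))
  }
  writeMatrixLibrary(sim$motifs, file.path(dir, "motifs.jaspar"))
  writeExpressionGct(sim$tpm, file.path(dir, "tpm.gct"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated dataset back from disk
#'
#' Inverse of [writeSimulation()] for every table the pipeline consumes
#' (the config is not round-tripped).
#'
#' @param dir directory written by [writeSimulation()].
#' @return list shaped like [simulateRegulatoryData()] output (without
#'   `config`).
#' @export
readSimulation <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- setNames(as.character(fa), sub(" .*", "", names(fa)))
  tsv <- function(name, ...) {
    read.table(file.path(dir, name), sep = "\t", header = TRUE,
               stringsAsFactors = FALSE, check.names = FALSE, ...)
  }
  chrom_files <- list.files(dir, pattern = "^chromhmm_.*\\.bed$",
                            full.names = TRUE)
  chromhmm <- do.call(rbind, lapply(chrom_files, function(f) {
    bs <- gsub("_", " ", sub("^chromhmm_(.*)\\.bed$", "\\1", basename(f)))
    readBed(f, biosample = bs)
  }))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  list(genome = genome, genes = tsv("genes.tsv"),
       motifs = readMatrixLibrary(file.path(dir, "motifs.jaspar"), "jaspar"),
       peaks = readBed(file.path(dir, "peaks.bed")),
       variants = tsv("variants.tsv"), pool = tsv("pool.tsv"),
       associations = tsv("associations.tsv"), ld = tsv("ld.tsv"),
       gwas_pics = readPicsTable(file.path(dir, "gwas_pics.tsv"), "gwas"),
       eqtl_pics = readPicsTable(file.path(dir, "eqtl_pics.tsv"), "eqtl"),
       chromhmm = chromhmm,
       tpm = readExpressionMatrix(file.path(dir, "tpm.gct")),
       tftarget = tsv("tftarget.tsv"),
       tissue_map = tsv("tissue_map.tsv"),
       truth = truth)
}
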