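test_that("config echo and validation", {
  cfg <- simulationConfig(seed = 3, n_genes = 10L)
  expect_equal(cfg$n_genes, 10L)
  expect_error(simulationConfig(1, nonsense = 2), "unknown config")
  expect_error(simulationConfig(1, n_planted_causal = 50L), "n_loci")
})

test_that("simulated genome has the configured CpG depletion and gene count", {
  sim <- getSim(21)
  cfg <- sim$config
  expect_equal(nrow(sim$genes), cfg$n_genes)
  expect_true(all(sim$genes$start >= 1 &
                    sim$genes$end <= cfg$chrom_length))
  expect_true(all(sim$genes$tss >= sim$genes$start &
                    sim$genes$tss <= sim$genes$end))
  g <- sim$genome[[1]]
  n <- nchar(g)
  cg <- sum(gregexpr("CG", g, fixed = TRUE)[[1]] > 0)
  pC <- lengths(gregexpr("C", g)) / n
  pG <- lengths(gregexpr("G", g)) / n
  ratio <- cg / (pC * pG * n)
  expect_lt(abs(ratio - cfg$cpg_depletion), 0.05)
})

test_that("simulation is deterministic under the seed", {
  s1 <- simulateRegulatoryData(simulationConfig(seed = 77,
                                                chrom_length = 200000L,
                                                pool_size = 100L))
  s2 <- simulateRegulatoryData(simulationConfig(seed = 77,
                                                chrom_length = 200000L,
                                                pool_size = 100L))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSimulation(s1, d1)
  writeSimulation(s2, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("written files round-trip into the same tables", {
  sim <- getSim(21)
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  back <- readSimulation(dir)
  expect_identical(back$genome, sim$genome)
  expect_equal(back$variants, sim$variants)
  expect_equal(back$ld, sim$ld)
  expect_equal(back$gwas_pics$pics_prob, sim$gwas_pics$pics_prob)
  expect_equal(back$peaks[, c("chrom", "start", "end")],
               sim$peaks[, c("chrom", "start", "end")])
  expect_equal(back$tpm, sim$tpm)
  expect_equal(length(back$motifs), length(sim$motifs))
  expect_equal(motifCounts(back$motifs[[3]]), motifCounts(sim$motifs[[3]]))
  expect_setequal(back$truth$causal, sim$truth$causal)
  expect_equal(nrow(back$chromhmm), nrow(sim$chromhmm))
})

test_that("planted structures satisfy their construction guarantees", {
  sim <- getSim(21)
  cfg <- sim$config
  expect_equal(length(sim$motifs), cfg$n_motifs)
  ics <- vapply(sim$motifs, informationContent, numeric(1))
  lens <- vapply(sim$motifs, motifLength, numeric(1))
  expect_true(all(lens >= cfg$motif_length_range[1] &
                    lens <= cfg$motif_length_range[2]))
  expect_true(all(ics > 8 & ics < 18)) # around the 10-16 bit target
  # every planted binding variant lies inside a peak, with ref = genome base
  bind <- merge(sim$truth$binding, sim$variants, by = "variant_id")
  for (i in seq_len(nrow(bind))) {
    p <- sim$peaks[sim$peaks$chrom == bind$chrom[i] &
                     sim$peaks$start < bind$pos[i] &
                     sim$peaks$end >= bind$pos[i], ]
    expect_equal(nrow(p), 1L)
    expect_identical(
      fetchSequence(sim$genome, bind$chrom[i], bind$pos[i], bind$pos[i]),
      bind$ref[i])
  }
  # disrupt variants weaken the true motif under direct scoring
  motifs <- setNames(sim$motifs, vapply(sim$motifs, motifId, character(1)))
  bg <- estimateMarkov(randomSeq(4000), 0, 1)
  w <- buildVariantWindows(sim$genome, bind, 30)
  cache <- new.env()
  for (i in seq_len(nrow(bind))) {
    res <- scanVariants(w[w$variant_id == bind$variant_id[i], ],
                        motifs[bind$matrix_id[i]], bg, cache = cache)
    expect_gt(res$weight_diff, 1)
    expect_identical(res$effect, bind$effect[i])
  }
  # pool never overlaps peaks, distractor eQTLs never hit GWAS variants
  pconv <- bedToOneBased(sim$peaks$start, sim$peaks$end)
  pr <- GenomicRanges::GRanges(sim$peaks$chrom,
                               IRanges::IRanges(pconv$start, pconv$end))
  qr <- GenomicRanges::GRanges(sim$pool$chrom,
                               IRanges::IRanges(sim$pool$pos, sim$pool$pos))
  expect_equal(sum(GenomicRanges::countOverlaps(qr, pr)), 0L)
  distr <- setdiff(sim$eqtl_pics$variant_id,
                   c(sim$truth$coloc$variant_id,
                     sim$truth$triples$variant_id))
  expect_false(any(distr %in% sim$gwas_pics$variant_id))
})
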