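test_that("PWM frequencies normalize each column with the pseudocount", {
  expect_equal(pwmFrequencies(matrix(c(10, 0, 0, 0), 4, 1), 0)[, 1],
               c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(pwmFrequencies(matrix(1, 4, 1), 7)[, 1]),
               rep(0.25, 4))
  expect_equal(unname(pwmFrequencies(matrix(c(3, 1, 0, 0), 4, 1), 1)[, 1]),
               c(3.25, 1.25, 0.25, 0.25) / 5)
})

test_that("site weight is the per-position log2 ratio sum", {
  bg <- estimateMarkov("ACGT", 0, 0, revcomp = FALSE) # uniform
  unif <- pwmFrequencies(matrix(1, 4, 4), 0)
  expect_equal(siteWeight(unif, bg, "ACGT"), 0)
  cnt <- matrix(c(8, 1, 1, 0,
                  0, 9, 1, 0,
                  1, 0, 8, 1,
                  0, 1, 0, 9), nrow = 4)
  f <- pwmFrequencies(cnt, 1)
  manual <- sum(log2(f[cbind(c(1, 2, 3, 4), 1:4)]) - log2(0.25))
  expect_equal(siteWeight(f, bg, "ACGT"), manual, tolerance = 1e-12)
  expect_message(na <- siteWeight(f, bg, "ACNT"), "ambiguous")
  expect_true(is.na(na))
})

test_that("weight p-values match exhaustive enumeration and are monotone", {
  set.seed(12)
  bg1 <- estimateMarkov(randomSeq(500), 1, 1)
  m <- randomMotif(4)
  f <- pwmFrequencies(m, 1)
  d <- scoreDistribution(f, bg1, 0.01)
  ws <- seq(-12, 8, length.out = 60)
  ps <- tailProbability(d, ws)
  expect_true(all(diff(ps) <= 1e-12))
  expect_equal(tailProbability(d, -Inf), 1)
  expect_equal(tailProbability(d, -1e4), 1)
  expect_equal(tailProbability(d, 1e4), 1e-16) # clamped floor
  for (w in c(-6, -2, 0, 2, 4)) {
    lo <- bruteTailProbability(f, bg1, w + 0.02)
    hi <- bruteTailProbability(f, bg1, w - 0.02)
    expect_gte(tailProbability(d, w), lo - 1e-12)
    expect_lte(tailProbability(d, w), hi + 1e-12)
  }
})

test_that("scanning is strand symmetric and ties break to plus strand", {
  set.seed(13)
  g <- c(chr1 = randomSeq(200))
  v <- data.frame(variant_id = "v", chrom = "chr1", pos = 100,
                  ref = substr(g, 100, 100),
                  alt = setdiff(c("A", "C", "G", "T"),
                                substr(g, 100, 100))[1])
  w <- buildVariantWindows(g, v, flank = 20)
  bg <- estimateMarkov(randomSeq(1000), 1, 1)
  m <- randomMotif(6)
  res <- scanVariants(w, list(m), bg)
  # scanning the reverse-complemented window must swap strands only
  wrc <- w
  wrc$ref_seq <- regvar:::revcompStr(w$ref_seq)
  wrc$alt_seq <- regvar:::revcompStr(w$alt_seq)
  wrc$variant_offset <- nchar(w$ref_seq) - 1L - w$variant_offset
  resrc <- scanVariants(wrc, list(m), bg)
  expect_equal(res$ref_weight, resrc$ref_weight, tolerance = 1e-9)
  expect_equal(res$alt_weight, resrc$alt_weight, tolerance = 1e-9)
  expect_equal(res$pval_ratio, resrc$pval_ratio, tolerance = 1e-6)

  # palindromic matrix: both strands tie, plus strand reported
  pal <- PWMotif("P", "P", matrix(c(
    9, 0, 0, 0,
    0, 9, 0, 0,
    0, 0, 9, 0,
    0, 0, 0, 9), nrow = 4) + 0.5)
  resp <- scanVariant(pal, bg, w)
  expect_identical(resp$ref_strand, "+")
})

test_that("the best site always covers the variant base", {
  set.seed(14)
  g <- c(chr1 = randomSeq(200))
  v <- data.frame(variant_id = "v", chrom = "chr1", pos = 100,
                  ref = substr(g, 100, 100), alt = "A")
  v$alt <- setdiff(c("C", "G", "T", "A"), v$ref)[1]
  w <- buildVariantWindows(g, v, flank = 15)
  bg <- estimateMarkov(randomSeq(800), 0, 1)
  for (L in c(4, 7)) {
    m <- randomMotif(L)
    res <- scanVariants(w, list(m), bg)
    for (col in c("ref_offset", "alt_offset")) {
      off <- res[[col]]
      expect_true(off <= w$variant_offset &&
                    off + L > w$variant_offset)
    }
  }
  # a matrix longer than the window is skipped with a warning
  expect_warning(out <- scanVariants(w, list(randomMotif(40)), bg),
                 "longer than the scan window")
  expect_equal(nrow(out), 0L)
})

test_that("retention filters are strict on all four thresholds", {
  base <- data.frame(variant_id = "v", matrix_id = "m",
                     ref_weight = 5, alt_weight = 2,
                     ref_pvalue = 1e-4, alt_pvalue = 5e-3,
                     weight_diff = 3, pval_ratio = 50)
  expect_equal(nrow(applyScanFilters(base)), 1L)
  drop_ratio <- transform(base, pval_ratio = 10)
  expect_equal(nrow(applyScanFilters(drop_ratio)), 0L)
  drop_diff <- transform(base, weight_diff = 0)
  expect_equal(nrow(applyScanFilters(drop_diff)), 0L)
  drop_w <- transform(base, ref_weight = 1, alt_weight = 0.5)
  expect_equal(nrow(applyScanFilters(drop_w)), 0L)
  drop_p <- transform(base, ref_pvalue = 1e-3, alt_pvalue = 2e-3)
  expect_equal(nrow(applyScanFilters(drop_p)), 0L)
})

test_that("planted motif-flipping variants pass the filters and effects match", {
  sim <- getSim(21)
  motifs <- sim$motifs
  names(motifs) <- vapply(motifs, motifId, character(1))
  bg <- estimateMarkov(vapply(seq_len(nrow(sim$peaks)), function(i)
    fetchSequence(sim$genome, sim$peaks$chrom[i], sim$peaks$start[i] + 1,
                  sim$peaks$end[i]), character(1)), 2, 1)
  truth <- sim$truth$binding
  vars <- sim$variants[match(truth$variant_id, sim$variants$variant_id), ]
  w <- buildVariantWindows(sim$genome, vars, 30)
  cache <- new.env()
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    res <- scanVariants(w[w$variant_id == truth$variant_id[i], ],
                        motifs[truth$matrix_id[i]], bg, cache = cache)
    kept <- applyScanFilters(res)
    if (nrow(kept)) {
      hits <- hits + 1
      expect_identical(kept$effect, truth$effect[i])
    }
  }
  expect_gte(hits / nrow(truth), 0.9)
})
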