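test_that("order-0 estimation matches base composition", {
  bg <- estimateMarkov("ACGT", 0, 0, revcomp = FALSE)
  expect_equal(unname(bgTransitions(bg)[1, ]), rep(0.25, 4))
  bgA <- estimateMarkov("AAAA", 0, 0, revcomp = FALSE)
  expect_equal(unname(bgTransitions(bgA)[1, ]), c(1, 0, 0, 0))
  # with reverse-complement augmentation the same input is strand-balanced
  bgA2 <- estimateMarkov("AAAA", 0, 0)
  expect_equal(unname(bgTransitions(bgA2)[1, c("A", "T")]), c(0.5, 0.5))
})

test_that("order-2 counts match hand counting on a short sequence", {
  s <- "AACGTACGTAACCGGTTACG" # 20 bp
  bg <- estimateMarkov(s, 2, 0, revcomp = FALSE)
  # circular counting: contexts wrap, so every position has a successor;
  # hand-count occurrences of context "AC" -> next base
  ext <- paste0(s, substr(s, 1, 2))
  ctxs <- substring(ext, 1:20, 3:22)
  ac_next <- table(substr(ctxs[startsWith(ctxs, "AC")], 3, 3))
  tr <- bgTransitions(bg)["AC", ]
  expect_equal(unname(tr["G"]), unname(ac_next[["G"]] / sum(ac_next)))
  expect_true(all(abs(rowSums(bgTransitions(bg))[bgStationary(bg) > 0] - 1)
                  < 1e-9))
  expect_equal(sum(bgStationary(bg)), 1, tolerance = 1e-12)
})

test_that("estimated models are exactly strand symmetric", {
  set.seed(7)
  for (order in 0:2) {
    bg <- estimateMarkov(randomSeq(2000), order, 1)
    for (i in 1:10) {
      s <- randomSeq(18)
      expect_equal(sequenceLogProb(bg, s),
                   sequenceLogProb(bg, regvar:::revcompStr(s)),
                   tolerance = 1e-9)
    }
  }
})

test_that("model probabilities sum to one over all words", {
  set.seed(8)
  for (order in 0:2) {
    bg <- estimateMarkov(randomSeq(1500), order, 1)
    L <- 5
    words <- apply(as.matrix(expand.grid(rep(list(c("A", "C", "G", "T")), L))),
                   1, paste, collapse = "")
    total <- sum(vapply(words, function(w) 2^sequenceLogProb(bg, w),
                        numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("sequence log-probability follows the chain rule", {
  bg <- estimateMarkov("ACGT", 0, 0, revcomp = FALSE)
  expect_equal(sequenceLogProb(bg, "ACGT"), -8)
  bgA <- estimateMarkov("AAAA", 0, 0, revcomp = FALSE)
  expect_equal(sequenceLogProb(bgA, "AAA"), 0)
  expect_equal(sequenceLogProb(bgA, "AAT"), -Inf)
  # order-1 toy model vs a manual chain-rule product
  bg1 <- estimateMarkov("AACAACAAC", 1, 0, revcomp = FALSE)
  tr <- bgTransitions(bg1)
  st <- bgStationary(bg1)
  manual <- log2(st[["A"]]) + log2(tr["A", "A"]) + log2(tr["A", "C"]) +
    log2(tr["C", "A"])
  expect_equal(sequenceLogProb(bg1, "AACA"), manual, tolerance = 1e-12)
  expect_error(sequenceLogProb(bg1, "A"), "longer than")
  expect_error(estimateMarkov("AC", 5, 1), "larger than")
})

test_that("variant windows carry the flank, the offset and both alleles", {
  g <- c(chr1 = "AACGTAA")
  v <- data.frame(variant_id = "v1", chrom = "chr1", pos = 4,
                  ref = "G", alt = "T")
  w <- buildVariantWindows(g, v, flank = 2)
  expect_identical(w$ref_seq, "ACGTA")
  expect_identical(w$alt_seq, "ACTTA")
  expect_equal(w$variant_offset, 2L)

  g2 <- c(chr1 = paste(rep("ACGT", 40), collapse = ""))
  v2 <- data.frame(variant_id = "v2", chrom = "chr1", pos = 80,
                   ref = "T", alt = "A")
  w2 <- buildVariantWindows(g2, v2, flank = 30)
  expect_equal(nchar(w2$ref_seq), 61L)
  expect_equal(w2$variant_offset, 30L)

  vbad <- data.frame(variant_id = "v3", chrom = "chr1", pos = 4,
                     ref = "A", alt = "T")
  expect_error(buildVariantWindows(g, vbad), "reference mismatch")
  vindel <- data.frame(variant_id = "v5", chrom = "chr1", pos = 4,
                       ref = "GT", alt = "G")
  expect_error(buildVariantWindows(g, vindel), "single A/C/G/T")
  vsame <- data.frame(variant_id = "v6", chrom = "chr1", pos = 4,
                      ref = "G", alt = "G")
  expect_error(buildVariantWindows(g, vsame), "ref != alt")
  vtrunc <- data.frame(variant_id = "v4", chrom = "chr1", pos = 2,
                       ref = "A", alt = "T")
  expect_warning(wt <- buildVariantWindows(g, vtrunc, flank = 4), "truncated")
  expect_equal(wt$variant_offset, 1L)
})
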