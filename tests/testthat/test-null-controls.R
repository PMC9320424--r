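test_that("matrix permutation conserves column multisets and information", {
  set.seed(15)
  for (i in 1:100) {
    m <- randomMotif(sample(3:12, 1))
    perms <- permuteMatrix(m, 5, seed = i)
    ic0 <- informationContent(m)
    comp0 <- sort(as.vector(motifCounts(m)))
    for (p in perms) {
      cnt <- motifCounts(p)
      expect_equal(sort(as.vector(cnt)), comp0)
      # per-column multisets preserved up to column reordering
      cols0 <- sort(apply(motifCounts(m), 2, function(x)
        paste(sort(x), collapse = ",")))
      cols1 <- sort(apply(cnt, 2, function(x)
        paste(sort(x), collapse = ",")))
      expect_identical(cols1, cols0)
      expect_equal(informationContent(p), ic0, tolerance = 1e-9)
    }
  }
  # determinism under seed, L = 1 edge case
  m1 <- randomMotif(1)
  expect_equal(motifCounts(permuteMatrix(m1, 2, seed = 4)[[2]]),
               motifCounts(permuteMatrix(m1, 2, seed = 4)[[2]]))
})

test_that("match attributes count TSS distance, density and LD partners", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(11000, 50000, 90000))
  ld <- data.frame(variant_a = c("v1", "v1", "x"),
                   variant_b = c("p1", "p2", "v1"),
                   r2 = c(0.15, 0.09, 0.5))
  v <- data.frame(variant_id = c("v1", "v2"), chrom = c("chr1", "chr2"),
                  pos = c(10000, 5), ref = "A", alt = "C",
                  consequence_terms = c("intron_variant", "missense_variant"))
  at <- computeMatchAttributes(v, genes, ld)
  expect_equal(at$tss_distance[1], 1000)
  expect_equal(at$gene_density[1], 2L) # TSS at 1 kb and 40 kb; 80 kb is out
  expect_equal(at$ld_count[1], 2L)     # r2 0.15 and 0.5; 0.09 excluded
  expect_true(is.na(at$tss_distance[2])) # no genes on chr2
  expect_identical(at$coding_class, c("non-coding", "coding"))
  expect_identical(unique(at$variant_type), "SNV")
})

test_that("strict matched sampling honours every window and exclusions", {
  set.seed(16)
  n <- 400
  pool <- data.frame(
    variant_id = paste0("p", 1:n), chrom = sample(c("chr1", "chr2"), n, TRUE),
    tss_distance = runif(n, 0, 30000), gene_density = sample(0:8, n, TRUE),
    ld_count = sample(0:40, n, TRUE), coding_class = "non-coding",
    variant_type = "SNV")
  targets <- pool[sample(n, 12), ]
  targets$variant_id <- paste0("t", 1:12)
  asg <- sampleMatchedControls(targets, pool, "strict", ratio = 10, seed = 2)
  expect_true(all(!asg$control_variant_id %in% targets$variant_id))
  for (i in seq_len(nrow(asg))) {
    t <- targets[targets$variant_id == asg$target_variant_id[i], ]
    ctl <- pool[pool$variant_id == asg$control_variant_id[i], ]
    expect_identical(ctl$chrom, t$chrom)
    expect_lte(abs(ctl$tss_distance - t$tss_distance), 5000)
    expect_lte(abs(ctl$gene_density - t$gene_density), 5)
    expect_lte(abs(ctl$ld_count - t$ld_count), 50)
    expect_identical(ctl$coding_class, t$coding_class)
    expect_identical(ctl$variant_type, t$variant_type)
  }
  # determinism
  asg2 <- sampleMatchedControls(targets, pool, "strict", ratio = 10, seed = 2)
  expect_identical(asg, asg2)
  # a target cloned across the pool gets the full ratio
  clone_pool <- targets[rep(1, 30), ]
  clone_pool$variant_id <- paste0("c", 1:30)
  a1 <- sampleMatchedControls(targets[1, ], clone_pool, "strict", 10, seed = 1)
  expect_equal(nrow(a1), 10L)
  # relaxed mode ignores the numeric windows but keeps class/type
  far_pool <- pool
  far_pool$tss_distance <- pool$tss_distance + 1e6
  ar <- sampleMatchedControls(targets, far_pool, "relaxed", 10, seed = 3)
  expect_gt(nrow(ar), 0)
  none <- transform(far_pool, coding_class = "coding")
  expect_message(a0 <- sampleMatchedControls(targets, none, "relaxed", 10,
                                             seed = 3), "no eligible")
  expect_equal(nrow(a0), 0L)
})

test_that("one-sided rank test matches exact enumeration", {
  expect_equal(wilcoxonGreater(c(10, 11), c(1, 2)), 1 / 6)
  expect_gte(wilcoxonGreater(c(3, 1, 2), c(3, 1, 2)), 0.5)
  set.seed(17)
  for (i in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    if (n + m > 10) next
    x <- sample(seq(1, 100), n); y <- sample(setdiff(seq(1, 100), x), m)
    expect_equal(wilcoxonGreater(x, y), bruteWilcoxonGreater(x, y),
                 tolerance = 1e-12)
  }
  # exact and approximate paths agree closely for moderate samples
  for (i in 1:10) {
    x <- rnorm(6) + 1; y <- rnorm(6)
    exact <- bruteWilcoxonGreater(x, y)
    approx <- suppressWarnings(
      wilcox.test(x, y, alternative = "greater", exact = FALSE,
                  correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("Shapiro-Wilk wrapper flags degenerate input and heavy tails", {
  expect_true(is.na(shapiroWilkCheck(c(1, 2))))
  expect_true(is.na(shapiroWilkCheck(rep(3, 10))))
  set.seed(18)
  rejections <- vapply(1:40, function(i)
    shapiroWilkCheck(exp(rnorm(100, 0, 2))) < 0.05, logical(1))
  expect_gte(mean(rejections), 0.95)
  # under normal data the p-values are close to uniform
  ps <- vapply(1:60, function(i) shapiroWilkCheck(rnorm(100)), numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("motif confirmation separates planted from null ratio sets", {
  set.seed(19)
  nullRatios <- function(n) 10 * exp(rexp(n, 2))
  mk <- function(ids, gen) do.call(rbind, lapply(ids, function(id)
    data.frame(matrix_id = id, pval_ratio = gen(30))))
  controls <- list(permuted = mk(c("A", "B"), nullRatios),
                   matched10 = mk(c("A", "B"), nullRatios),
                   matched1000 = mk(c("A", "B"), nullRatios))
  observed <- rbind(
    data.frame(matrix_id = "A", variant_id = paste0("v", 1:6),
               pval_ratio = c(5e3, 8e3, 1e4, 2e4, 4e3, 6e3)),
    data.frame(matrix_id = "B", variant_id = paste0("u", 1:6),
               pval_ratio = nullRatios(6)))
  for (method in c("quantile", "wilcoxon")) {
    out <- confirmMotifPairs(observed, controls, method = method)
    tab <- out$motifs
    expect_true(tab$confirmed[tab$matrix_id == "A"])
    expect_true(all(out$pairs$matrix_id == "A" |
                      out$pairs$variant_id %in% paste0("u", 1:6)))
  }
  # null observed set stays unconfirmed in most seeded repetitions
  wrong <- 0
  for (s in 1:30) {
    set.seed(100 + s)
    obs0 <- data.frame(matrix_id = "B", variant_id = paste0("w", 1:8),
                       pval_ratio = nullRatios(8))
    ctl0 <- list(permuted = mk("B", nullRatios),
                 matched10 = mk("B", nullRatios),
                 matched1000 = mk("B", nullRatios))
    out0 <- confirmMotifPairs(obs0, ctl0, method = "wilcoxon")
    wrong <- wrong + out0$motifs$confirmed
  }
  expect_lte(wrong / 30, 0.10)
  # a motif without control observations is flagged, never confirmed
  out2 <- confirmMotifPairs(
    data.frame(matrix_id = "C", variant_id = "v", pval_ratio = 1e5),
    list(permuted = mk("A", nullRatios), matched10 = mk("A", nullRatios),
         matched1000 = mk("A", nullRatios)))
  expect_true(out2$motifs$unconfirmable)
  expect_false(out2$motifs$confirmed)
  # two-stage order: a motif rejected at stage one is never confirmed
  expect_true(all(!out2$motifs$confirmed | out2$motifs$stage1))
})
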