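test_that("JASPAR parsing preserves counts and validates records", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TFA",
    "A  [ 3 10  0  5  1  2 ]",
    "C  [ 1  0  9  0  0  8 ]",
    "G  [ 0  0  1  5  9  0 ]",
    "T  [ 6  0  0  0  0  0 ]"), path)
  mats <- readMatrixLibrary(path, "jaspar")
  expect_length(mats, 1L)
  m <- mats[[1]]
  expect_s4_class(m, "PWMotif")
  expect_equal(motifLength(m), 6L)
  expect_identical(motifId(m), "MA0001.1")
  expect_identical(tfName(m), "TFA")
  expect_equal(motifCounts(m)["A", ], c(3, 10, 0, 5, 1, 2))

  empty <- withr::local_tempfile(fileext = ".jaspar")
  file.create(empty)
  expect_warning(out <- readMatrixLibrary(empty, "jaspar"), "empty")
  expect_identical(out, list())

  bad <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 x", "A [ 1 x ]", "C [ 1 1 ]", "G [ 1 1 ]",
               "T [ 1 1 ]"), bad)
  expect_error(readMatrixLibrary(bad, "jaspar"), "line")

  zerocol <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 x", "A [ 1 0 ]", "C [ 1 0 ]", "G [ 1 0 ]",
               "T [ 1 0 ]"), zerocol)
  expect_error(readMatrixLibrary(zerocol, "jaspar"), "positive")
})

test_that("TRANSFAC parsing and JASPAR round trip agree", {
  path <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c(
    "AC M0001", "ID m1", "DE TFB", "P0 A C G T",
    "01 1 2 3 4", "02 8 0 0 2", "//"), path)
  mats <- readMatrixLibrary(path, "transfac")
  expect_equal(motifCounts(mats[[1]]),
               matrix(c(1, 2, 3, 4, 8, 0, 0, 2), nrow = 4,
                      dimnames = list(c("A", "C", "G", "T"), NULL)))
  out <- withr::local_tempfile(fileext = ".jaspar")
  writeMatrixLibrary(mats, out)
  back <- readMatrixLibrary(out, "jaspar")
  expect_equal(motifCounts(back[[1]]), motifCounts(mats[[1]]))
  expect_identical(motifId(back[[1]]), "M0001")
})

test_that("fetchSequence honours 1-based inclusive coordinates", {
  g <- c(chr1 = "ACGT")
  expect_identical(fetchSequence(g, "chr1", 2, 3), "CG")
  expect_identical(fetchSequence(g, "chr1", 1, 4), "ACGT")
  expect_error(fetchSequence(g, "chr1", 0, 2), "out of bounds")
  expect_error(fetchSequence(g, "chrX", 1, 2), "unknown chromosome")
})

test_that("BED reading keeps 0-based half-open intervals and labels", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=foo", "# comment",
               "chr1\t10\t20\tTssA", "chr2\t0\t5"), path)
  bed <- readBed(path, biosample = "b1")
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$start, c(10L, 0L))
  expect_identical(bed$name, c("TssA", NA_character_))
  expect_identical(unique(bed$biosample), "b1")

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t20\t10", bad)
  expect_error(readBed(bad), "start >= end")
})

test_that("BED coordinate conversion round-trips", {
  conv <- bedToOneBased(c(0L, 10L), c(5L, 20L))
  back <- oneBasedToBed(conv$start, conv$end)
  expect_equal(back$start, c(0L, 10L))
  expect_equal(back$end, c(5L, 20L))
})

test_that("expression matrix reading handles GCT and TSV dialects", {
  mat <- matrix(c(1.5, 0, 3, 2, 8, 0.25), nrow = 2,
                dimnames = list(c("g1", "g2"), c("T1", "T2", "T3")))
  gct <- withr::local_tempfile(fileext = ".gct")
  writeExpressionGct(mat, gct)
  expect_equal(readExpressionMatrix(gct), mat)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(mat), mat),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readExpressionMatrix(tsv), mat)

  dup <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("g1", "g1"), T1 = c(1, 2)),
              dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionMatrix(dup), "duplicate")

  neg <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = "g1", T1 = -1),
              neg, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readExpressionMatrix(neg), "negative")
})

test_that("PICS tables accept a configurable column mapping", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(rsid = c("v1", "v2"), lead = "v1",
                         prob = c(0.6, 0.2), tis = "Brain_Cortex",
                         gene = "G1"),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readPicsTable(path, "eqtl",
                       cols = c(variant_id = "rsid", locus_id = "lead",
                                pics_prob = "prob", tissue = "tis",
                                egene = "gene"))
  expect_equal(tab$variant_id, c("v1", "v2"))
  expect_equal(tab$pics_prob, c(0.6, 0.2))
  expect_identical(unique(tab$source), "eqtl")
})

test_that("background model serialization round-trips", {
  set.seed(1)
  bg <- estimateMarkov(randomSeq(800), 2, 1, label = "b")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBackgroundModel(bg, path)
  back <- readBackgroundModel(path)
  expect_equal(bgOrder(back), 2L)
  expect_identical(bgLabel(back), "b")
  expect_equal(bgTransitions(back), bgTransitions(bg), tolerance = 1e-12)
  expect_equal(bgStationary(back), bgStationary(bg), tolerance = 1e-12)
})

test_that("PWMotif and MarkovBackground validity catch bad objects", {
  expect_error(PWMotif("m", "t", matrix(-1, 4, 2)), "non-negative")
  expect_error(PWMotif("m", "t", matrix(0, 4, 2)), "positive")
  bg <- estimateMarkov("ACGTACGT", 1, 1)
  tr <- bgTransitions(bg)
  tr[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(methods::new("MarkovBackground", order = 1L,
                            transitions = tr, stationary = bgStationary(bg),
                            label = "x", pseudocount = 1),
               "sum to 1")
})
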