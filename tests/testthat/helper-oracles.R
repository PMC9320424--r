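## Independent oracles and small fixture builders shared across tests.

## brute-force weight distribution: enumerate every word of length L and
## every initial background context, chain-rule the probability and the
## weight. Independent of the DP implementation (no discretization).
bruteWeightTable <- function(pwm_freqs, bg) {
  k <- bgOrder(bg)
  L <- ncol(pwm_freqs)
  tr <- bgTransitions(bg)
  st <- bgStationary(bg)
  nctx <- nrow(tr)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  nw <- nrow(words)
  wt <- rep(0, nw * nctx)
  pr <- rep(st, each = nw)
  ctxi <- rep(seq_len(nctx), each = nw)
  for (j in seq_len(L)) {
    b <- rep(words[, j], nctx)
    p <- tr[cbind(ctxi, b)]
    wt <- wt + log2(pwm_freqs[b, j]) - log2(p)
    pr <- pr * p
    ctxi <- if (k == 0) ctxi else ((ctxi - 1L) %% 4^(k - 1)) * 4L + b
  }
  keep <- pr > 0
  list(weight = wt[keep], prob = pr[keep])
}

bruteTailProbability <- function(pwm_freqs, bg, w, table = NULL) {
  if (is.null(table)) table <- bruteWeightTable(pwm_freqs, bg)
  sum(table$prob[table$weight >= w - 1e-12])
}

## hypergeometric upper tail by explicit choose() summation
bruteHyperTail <- function(k, n_gwas, n_eqtl, N) {
  jmax <- min(n_gwas, n_eqtl)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(n_eqtl, j) * choose(N - n_eqtl, n_gwas - j)) /
    choose(N, n_gwas)
}

## exact one-sided rank-sum p by enumerating all assignments of the pooled
## values to the "observed" group
bruteWilcoxonGreater <- function(observed, control) {
  pooled <- c(observed, control)
  n <- length(observed)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  ws <- apply(combs, 2L, function(ix) sum(rank(pooled)[ix]) - n * (n + 1) / 2)
  mean(ws >= w_obs)
}

randomMotif <- function(L, id = "M1", tf = "TF1") {
  cnt <- matrix(stats::rgamma(4 * L, shape = 1) * 20, nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  PWMotif(id, tf, cnt)
}

randomSeq <- function(n, prob = c(.3, .2, .2, .3)) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = prob), collapse = "")
}

toyGenome <- function() {
  set.seed(99)
  c(chr1 = randomSeq(400), chr2 = randomSeq(300))
}

## cache simulated datasets across test files (deterministic per seed)
.simCache <- new.env(parent = emptyenv())
getSim <- function(seed, ...) {
  key <- paste0("s", seed, paste(c(...), collapse = "_"))
  if (is.null(.simCache[[key]])) {
    .simCache[[key]] <- simulateRegulatoryData(simulationConfig(seed, ...))
  }
  .simCache[[key]]
}
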