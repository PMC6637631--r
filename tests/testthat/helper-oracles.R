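# Independent brute-force oracles used across the suite. These
# deliberately avoid the package's vectorised code paths.

# co-occurrence by explicit pairwise set intersection
bruteCooccurrence <- function(R0) {
  m <- nrow(R0)
  out <- matrix(0L, m, m, dimnames = list(rownames(R0), rownames(R0)))
  for (k in seq_len(m)) for (r in seq_len(m)) {
    if (k != r && any(R0[k, ] == 1 & R0[r, ] == 1)) out[k, r] <- 1L
  }
  out
}

# literal double-loop evaluation of the top-K recommender sums
bruteRecommender <- function(sim, R0, k) {
  m <- nrow(sim)
  out <- matrix(0, m, ncol(R0), dimnames = dimnames(R0))
  for (t in seq_len(m)) {
    top <- order(sim[t, ], decreasing = TRUE)[seq_len(min(k, m - 1))]
    for (u in seq_len(ncol(R0))) {
      for (mt in seq_len(m)) {
        if (R0[mt, u] == 1 && mt %in% top) out[t, u] <- out[t, u] + sim[t, mt]
      }
    }
  }
  out
}

# pair score composed literally from the conditional probabilities
# (prior odds, per-neighbour posterior ratios with Laplace-smoothed
# counts, decay exponent on recommended-neighbour evidence)
oraclePairScore <- function(cn1, cn2, evidence, priors, alpha) {
  S <- priors$p1 / priors$p0
  for (m in cn1) {
    ev <- evidence[evidence$miRNA == m, ]
    pE1m <- (ev$nPlus + 1) / ((ev$nPlus + 1) + (ev$nMinus + 1))
    pE0m <- (ev$nMinus + 1) / ((ev$nPlus + 1) + (ev$nMinus + 1))
    S <- S * (pE1m * priors$p0) / (pE0m * priors$p1)
  }
  for (m in cn2) {
    ev <- evidence[evidence$miRNA == m, ]
    pE1m <- (ev$nPlus + 1) / ((ev$nPlus + 1) + (ev$nMinus + 1))
    pE0m <- (ev$nMinus + 1) / ((ev$nPlus + 1) + (ev$nMinus + 1))
    S <- S * (priors$p0 / priors$p1) * (pE1m / pE0m)^alpha
  }
  S
}

# AUC as the Mann-Whitney concordance statistic (ties count 1/2)
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random binary adjacency with guaranteed nonzero margins
randomAdjacency <- function(nr, nc, p = 0.4) {
  A <- matrix(rbinom(nr * nc, 1, p), nr, nc,
              dimnames = list(sprintf("m%d", seq_len(nr)),
                              sprintf("u%d", seq_len(nc))))
  A[cbind(seq_len(nr), sample.int(nc, nr, replace = TRUE))] <- 1L
  A
}

# small random tripartite instance as association tables
randomTables <- function(nl = 5, nm = 8, nd = 4, pml = 0.35, pmd = 0.35,
                         pld = 0.3) {
  Aml <- randomAdjacency(nm, nl, pml)
  colnames(Aml) <- sprintf("l%d", seq_len(nl))
  Amd <- randomAdjacency(nm, nd, pmd)
  colnames(Amd) <- sprintf("d%d", seq_len(nd))
  Y <- matrix(rbinom(nl * nd, 1, pld), nl, nd,
              dimnames = list(colnames(Aml), colnames(Amd)))
  if (sum(Y) == 0) Y[1, 1] <- 1L
  if (sum(Y) == length(Y)) Y[1, 1] <- 0L
  toTab <- function(A, kind) {
    idx <- which(A == 1, arr.ind = TRUE)
    associationTable(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]], kind)
  }
  list(ml = toTab(Aml, "miRNA-lncRNA"), md = toTab(Amd, "miRNA-disease"),
       ld = toTab(Y, "lncRNA-disease"))
}

# write an association table to a temp file and return the path
tmpTable <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
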