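# updated toy network plus two known associations, used across blocks
.toyUpdated <- function() {
  toy <- toyNetwork()
  cf <- applyCollaborativeFiltering(toy$network)
  net <- cf$network
  ld <- data.frame(from = c("l1", "l2"), to = c("d1", "d2"),
                   layer = "ld", provenance = "original",
                   stringsAsFactors = FALSE)
  net@edges <- rbind(net@edges, ld)
  validObject(net)
  net
}

test_that("prior odds follow the known-association fraction", {
  pr <- computePriors(3, 2, 2)
  expect_equal(pr$p1, 0.75)
  expect_equal(pr$odds, 3)
  # realistic scale: 407 known pairs among 77 x 95
  pr2 <- computePriors(407, 77, 95)
  expect_equal(pr2$p1, 407 / 7315)
  expect_equal(pr2$odds, (407 / 7315) / (1 - 407 / 7315))
  expect_error(computePriors(0, 2, 2), "degenerate prior")
  expect_error(computePriors(4, 2, 2), "degenerate prior")
})

test_that("common neighbours split into original and recommended sets", {
  net <- .toyUpdated()
  # (l2, d2): m3 reached by two original edges; m4, m5 via recommended ones
  part <- neighborPartition(net, "l2", "d2")
  expect_setequal(part$cn1, "m3")
  expect_setequal(part$cn2, c("m4", "m5"))
  # a pair with no common neighbours yields two empty sets
  toy <- toyNetwork()
  part0 <- neighborPartition(toy$network, "l1", "d2")
  expect_length(part0$cn1, 0)
  expect_length(part0$cn2, 0)
})

test_that("cn1 and cn2 are disjoint and adjacency-consistent (random nets)", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      tabs <- randomTables()
      cf <- applyCollaborativeFiltering(buildTripartite(tabs$ml, tabs$md))
      net <- cf$network
      U <- mldMatrix(net, "all")
      l <- sample(lncRNAs(net), 1)
      d <- sample(diseases(net), 1)
      part <- neighborPartition(net, l, d)
      expect_length(intersect(part$cn1, part$cn2), 0)
      for (m in c(part$cn1, part$cn2)) {
        expect_true(U[m, l] == 1 && U[m, d] == 1)
      }
      # direct edge-scan oracle for cn1
      e <- edges(net, provenance = "original")
      adjL <- e$from[e$layer == "ml" & e$to == l]
      adjD <- e$from[e$layer == "md" & e$to == d]
      expect_setequal(part$cn1, intersect(adjL, adjD))
    }
  })
})

test_that("evidence counts enumerate known pairs around each miRNA", {
  # miRNA adjacent to 2 lncRNAs and 3 diseases, 2 of the 6 pairs known
  ml <- associationTable(c("m1", "m1"), c("l1", "l2"), "miRNA-lncRNA")
  md <- associationTable(c("m1", "m1", "m1"), c("d1", "d2", "d3"),
                         "miRNA-disease")
  ld <- associationTable(c("l1", "l2"), c("d1", "d3"), "lncRNA-disease")
  net <- buildTripartite(ml, md, ld)
  ev <- evidenceCounts(net)
  expect_equal(ev$nPlus[ev$miRNA == "m1"], 2)
  expect_equal(ev$nMinus[ev$miRNA == "m1"], 4)
  expect_equal(ev$degree[ev$miRNA == "m1"], 5)

  # minimal case: one adjacent lncRNA and disease, known-associated
  ml2 <- associationTable("m1", "l1", "miRNA-lncRNA")
  md2 <- associationTable("m1", "d1", "miRNA-disease")
  ld2 <- associationTable("l1", "d1", "lncRNA-disease")
  ev2 <- evidenceCounts(buildTripartite(ml2, md2, ld2))
  expect_equal(ev2$nPlus, 1)
  expect_equal(ev2$nMinus, 0)
})

test_that("nPlus + nMinus = nLnc * nDis on random networks", {
  withr::with_seed(43, {
    for (rep in 1:15) {
      tabs <- randomTables()
      net <- buildTripartite(tabs$ml, tabs$md, tabs$ld)
      ev <- evidenceCounts(net)
      expect_equal(ev$nPlus + ev$nMinus, ev$nLnc * ev$nDis)
      expect_true(all(ev$nPlus >= 0 & ev$nMinus >= 0))
    }
  })
})

test_that("pair score limits are forced by the formula", {
  pr <- computePriors(5, 4, 4)
  ev <- data.frame(miRNA = "mA", nLnc = 1, nDis = 1, nPlus = 1, nMinus = 0,
                   degree = 2)
  # single original neighbour with N+ = 1, N- = 0: S = odds * odds^-1 * 2
  expect_equal(pairScore(list(cn1 = "mA", cn2 = character()), ev, pr), 2)
  # empty neighbourhood: prior odds only
  expect_equal(pairScore(list(cn1 = character(), cn2 = character()), ev, pr),
               pr$odds)
  expect_error(pairScore(list(cn1 = "mA", cn2 = character()), ev, pr,
                         alpha = 0), "alpha")
  expect_error(pairScore(list(cn1 = "mA", cn2 = character()), ev, pr,
                         alpha = 1.5), "alpha")
})

test_that("pair score equals the conditional-probability oracle", {
  withr::with_seed(47, {
    for (rep in 1:30) {
      nm <- sample(3:8, 1)
      ev <- data.frame(
        miRNA = sprintf("m%d", seq_len(nm)),
        nLnc = sample(1:5, nm, TRUE), nDis = sample(1:5, nm, TRUE)
      )
      ev$nPlus <- vapply(ev$nLnc * ev$nDis,
                         function(n) sample(0:n, 1), numeric(1))
      ev$nMinus <- ev$nLnc * ev$nDis - ev$nPlus
      ev$degree <- ev$nLnc + ev$nDis
      pr <- computePriors(sample(1:10, 1), 6, 6)
      split <- sample(0:nm, 1)
      cn1 <- ev$miRNA[seq_len(split)]
      rest <- setdiff(ev$miRNA, cn1)
      cn2 <- rest[runif(length(rest)) < 0.5]
      alpha <- runif(1, 0.01, 1)
      part <- list(cn1 = cn1, cn2 = cn2)
      expect_equal(pairScore(part, ev, pr, alpha),
                   oraclePairScore(cn1, cn2, ev, pr, alpha))
    }
  })
})

test_that("score rises with nPlus and obeys the membership-swap identity", {
  pr <- computePriors(4, 5, 5)
  scoreAt <- function(np, nl = 3, nd = 4) {
    ev <- data.frame(miRNA = "mA", nLnc = nl, nDis = nd, nPlus = np,
                     nMinus = nl * nd - np, degree = nl + nd)
    pairScore(list(cn1 = "mA", cn2 = character()), ev, pr)
  }
  s <- vapply(0:12, scoreAt, numeric(1))
  expect_true(all(diff(s) > 0))

  # moving a miRNA from cn1 to cn2 divides S by ratio^(1 - alpha)
  ev <- data.frame(miRNA = "mA", nLnc = 3, nDis = 3, nPlus = 4, nMinus = 5,
                   degree = 6)
  alpha <- 0.3
  r <- (4 + 1) / (5 + 1)
  s1 <- pairScore(list(cn1 = "mA", cn2 = character()), ev, pr, alpha)
  s2 <- pairScore(list(cn1 = character(), cn2 = "mA"), ev, pr, alpha)
  expect_equal(s1 / s2, r^(1 - alpha))
})

test_that("as alpha -> 0 the recommended-evidence ratio washes out", {
  pr <- computePriors(4, 5, 5)
  ev <- data.frame(miRNA = "mA", nLnc = 4, nDis = 4, nPlus = 10, nMinus = 6,
                   degree = 8)
  s <- pairScore(list(cn1 = character(), cn2 = "mA"), ev, pr, alpha = 1e-6)
  # the cn2 factor S / odds should approach the constant 1/odds
  expect_equal(s / pr$odds, 1 / pr$odds, tolerance = 1e-4)
})

test_that("degree normalisation matches its closed forms", {
  expect_equal(normalizeScore(exp(1), degrees = 2), 0.5)
  expect_equal(normalizeScore(1, degrees = c(5, 7)), 0)
  S <- 3.7
  expect_equal(normalizeScore(S, degrees = c(3, 4)), log(S) / 12)
  expect_equal(normalizeScore(S), log(S))          # empty neighbourhood
  expect_equal(normalizeScore(100, degrees = 2, logBase = 10), 1)
  expect_error(normalizeScore(2, degrees = c(2, 0)), "positive")
})

test_that("vectorised scoring equals the scalar per-pair sweep", {
  withr::with_seed(53, {
    for (rep in 1:8) {
      tabs <- randomTables(nl = sample(3:6, 1), nm = sample(5:10, 1),
                           nd = sample(3:5, 1))
      cf <- applyCollaborativeFiltering(buildTripartite(tabs$ml, tabs$md))
      net <- cf$network
      lset <- unique(tabs$ld$source); dset <- unique(tabs$ld$target)
      eld <- data.frame(from = tabs$ld$source, to = tabs$ld$target,
                        layer = "ld", provenance = "original",
                        stringsAsFactors = FALSE)
      net@lncRNAs <- sort(unique(c(net@lncRNAs, lset)))
      net@diseases <- sort(unique(c(net@diseases, dset)))
      net@edges <- rbind(net@edges, eld)
      validObject(net)
      alpha <- runif(1, 0.05, 1)
      res <- scoreAllPairs(net, alpha = alpha)
      pr <- computePriors(nrow(tabs$ld), length(lncRNAs(net)),
                          length(diseases(net)))
      ev <- evidenceCounts(net)
      for (l in lncRNAs(net)) for (d in diseases(net)) {
        part <- neighborPartition(net, l, d)
        S <- pairScore(part, ev, pr, alpha)
        ks <- ev$degree[match(c(part$cn1, part$cn2), ev$miRNA)]
        expect_equal(rawScores(res)[l, d], S)
        expect_equal(normScores(res)[l, d], normalizeScore(S, ks))
      }
    }
  })
})

test_that("alpha only matters where recommended common neighbours exist", {
  net <- .toyUpdated()
  r1 <- normScores(scoreAllPairs(net, alpha = 1))
  r2 <- normScores(scoreAllPairs(net, alpha = 0.05))
  differs <- abs(r1 - r2) > 1e-12
  for (l in rownames(r1)) for (d in colnames(r1)) {
    if (differs[l, d]) {
      expect_gt(length(neighborPartition(net, l, d)$cn2), 0)
    }
  }
  expect_true(any(differs))
})
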