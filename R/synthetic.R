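#' Worked-example tripartite network
#'
#' The small 5-miRNA, 2-lncRNA, 2-disease network used throughout the
#' documentation to illustrate the collaborative-filtering stage: edges
#' m1-l1, m1-l2, m2-l1, m3-l2 (miRNA-lncRNA) and m1-d1, m2-d1, m3-d2,
#' m4-d2, m5-d1, m5-d2 (miRNA-disease). Its spliced adjacency matrix,
#' similarity matrix and recommender matrix have closed-form entries
#' (e.g. similarity(m1, m2) = 2/sqrt(6)) that the test-suite pins down.
#'
#' @return list with `ml`, `md` association tables and `network`, the
#'   assembled [TripartiteNetwork-class].
#' @export
toyNetwork <- function() {
  ml <- associationTable(
    c("m1", "m1", "m2", "m3"),
    c("l1", "l2", "l1", "l2"),
    "miRNA-lncRNA"
  )
  md <- associationTable(
    c("m1", "m2", "m3", "m4", "m5", "m5"),
    c("d1", "d1", "d2", "d2", "d1", "d2"),
    "miRNA-disease"
  )
  list(ml = ml, md = md, network = buildTripartite(ml, md))
}

#' Simulate a tripartite network with a planted association signal
#'
#' Entities are partitioned into functional modules (mimicking the
#' co-targeting structure of real miRNA interaction layers: a miRNA and
#' its targets cluster into pathways). The miRNA-lncRNA and
#' miRNA-disease layers are Bernoulli-sampled with a high within-module
#' density and a low between-module density; collaborative filtering
#' relies on exactly this kind of item co-occurrence structure, and an
#' unstructured (single-module) network is a degenerate input for it. A
#' lncRNA-disease pair is then declared a true association with
#' probability `baseRate`, boosted by `signalStrength` when the pair
#' shares at least `minShared` miRNA neighbours -- the association
#' signal flows through shared miRNA mediators, the mechanism the
#' common-neighbour scorer is designed to detect. Output is
#' deterministic given `seed`.
#'
#' @param nLnc,nMir,nDis entity counts.
#' @param nModules number of functional modules.
#' @param withinDensity,betweenDensity edge densities of the miRNA
#'   layers within and between modules, in `(0, 1)`. Setting them equal
#'   gives a flat (unstructured) random network.
#' @param baseRate baseline association probability for unboosted pairs.
#' @param signalStrength additive probability boost for pairs sharing at
#'   least `minShared` miRNA neighbours.
#' @param minShared shared-neighbour threshold for the boost.
#' @param seed integer seed; the same seed reproduces the same tables.
#' @return list with `ml`, `md`, `ld` association tables.
#' @export
simulateTripartite <- function(nLnc = 30, nMir = 40, nDis = 25,
                               nModules = 5, withinDensity = 0.5,
                               betweenDensity = 0.02,
                               baseRate = 0.01, signalStrength = 0.4,
                               minShared = 2, seed = 1) {
  stopifnot(nLnc >= 1, nMir >= 1, nDis >= 1, nModules >= 1,
            withinDensity > 0, withinDensity < 1,
            betweenDensity > 0, betweenDensity < 1,
            baseRate >= 0, signalStrength >= 0,
            baseRate + signalStrength <= 1, minShared >= 0)
  mir <- sprintf("m%03d", seq_len(nMir))
  lnc <- sprintf("l%03d", seq_len(nLnc))
  dis <- sprintf("d%03d", seq_len(nDis))
  withr::with_seed(as.integer(seed), {
    gMir <- sample.int(nModules, nMir, replace = TRUE)
    gLnc <- sample.int(nModules, nLnc, replace = TRUE)
    gDis <- sample.int(nModules, nDis, replace = TRUE)
    pML <- ifelse(outer(gMir, gLnc, "=="), withinDensity, betweenDensity)
    pMD <- ifelse(outer(gMir, gDis, "=="), withinDensity, betweenDensity)
    Aml <- matrix(stats::rbinom(length(pML), 1, pML), nMir, nLnc,
                  dimnames = list(mir, lnc))
    Amd <- matrix(stats::rbinom(length(pMD), 1, pMD), nMir, nDis,
                  dimnames = list(mir, dis))
    shared <- crossprod(Aml, Amd)  # lncRNA x disease shared-miRNA counts
    p <- baseRate + signalStrength * (shared >= minShared)
    Y <- matrix(stats::rbinom(length(p), 1, p), nrow(p), ncol(p),
                dimnames = dimnames(shared))
    if (!sum(Aml) || !sum(Amd) || !sum(Y)) {
      stop("configuration yielded zero edges in at least one layer")
    }
    toTable <- function(A, kind) {
      idx <- which(A == 1, arr.ind = TRUE)
      associationTable(rownames(A)[idx[, 1]], colnames(A)[idx[, 2]], kind)
    }
    list(
      ml = toTable(Aml, "miRNA-lncRNA"),
      md = toTable(Amd, "miRNA-disease"),
      ld = toTable(Y, "lncRNA-disease")
    )
  })
}

#' Simulate a rooted random disease DAG
#'
#' Nodes are laid down in order; each node after the first draws between
#' one and `maxParents` parents uniformly from the earlier nodes, so the
#' result is acyclic by construction.
#'
#' @param nodes either an integer node count or a character vector of
#'   labels (e.g. the diseases of a simulated network).
#' @param maxParents maximum number of parents per node.
#' @param seed integer seed.
#' @return a [DiseaseDAG-class].
#' @export
simulateDiseaseDAG <- function(nodes, maxParents = 2, seed = 1) {
  labels <- if (is.numeric(nodes)) sprintf("d%03d", seq_len(nodes)) else nodes
  stopifnot(length(labels) >= 1, maxParents >= 1)
  if (length(labels) == 1) {
    return(new("DiseaseDAG", nodes = labels,
               parents = data.frame(child = character(),
                                    parent = character())))
  }
  withr::with_seed(as.integer(seed), {
    links <- lapply(seq(2, length(labels)), function(i) {
      np <- sample.int(min(maxParents, i - 1), 1)
      par <- sample.int(i - 1, np)
      data.frame(child = labels[i], parent = labels[par],
                 stringsAsFactors = FALSE)
    })
  })
  parseDiseaseDAG(do.call(rbind, links))
}
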