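#' Prior odds of a lncRNA-disease association
#'
#' The prior probability of an association is the number of known
#' lncRNA-disease edges over the number of possible pairs
#' `nLnc * nDis`; the classifier works with the corresponding odds
#' `p1 / (1 - p1)`.
#'
#' @param nKnown number of known lncRNA-disease associations.
#' @param nLnc,nDis numbers of lncRNAs and diseases.
#' @return list with `p1`, `p0`, `odds`, `nKnown`, `nPairs`.
#' @export
computePriors <- function(nKnown, nLnc, nDis) {
  stopifnot(nLnc >= 1, nDis >= 1)
  nPairs <- nLnc * nDis
  if (nKnown <= 0 || nKnown >= nPairs) {
    stop("degenerate prior: known associations must satisfy 0 < n < nLnc*nDis")
  }
  p1 <- nKnown / nPairs
  list(p1 = p1, p0 = 1 - p1, odds = p1 / (1 - p1),
       nKnown = nKnown, nPairs = nPairs)
}

.priorsFromNetwork <- function(net) {
  computePriors(sum(net@edges$layer == "ld"),
                length(net@lncRNAs), length(net@diseases))
}

#' Partition the common-neighbour miRNAs of a pair
#'
#' Common neighbours reached from both endpoints through original edges
#' form `cn1`; common neighbours (in the updated network) with at least
#' one incident recommended edge form `cn2`. The two sets are disjoint.
#'
#' @param net updated [TripartiteNetwork-class] (after the
#'   collaborative-filtering stage).
#' @param l lncRNA label.
#' @param d disease label.
#' @return list with character vectors `cn1`, `cn2`.
#' @export
neighborPartition <- function(net, l, d) {
  stopifnot(l %in% net@lncRNAs, d %in% net@diseases)
  U <- mldMatrix(net, "all")
  O <- mldMatrix(net, "original")
  all <- rownames(U)[U[, l] == 1 & U[, d] == 1]
  cn1 <- rownames(O)[O[, l] == 1 & O[, d] == 1]
  list(cn1 = cn1, cn2 = setdiff(all, cn1))
}

#' Per-miRNA evidence counts in the updated network
#'
#' For each miRNA: the numbers of adjacent lncRNAs (`nLnc`) and diseases
#' (`nDis`) in the updated network, the number `nPlus` of known
#' lncRNA-disease associations whose two endpoints are both adjacent to
#' the miRNA, the complement `nMinus = nLnc*nDis - nPlus`, and the
#' degree `nLnc + nDis`.
#'
#' @param net updated [TripartiteNetwork-class]; its `ld` edges are the
#'   known associations.
#' @return data.frame with one row per miRNA, columns `miRNA`, `nLnc`,
#'   `nDis`, `nPlus`, `nMinus`, `degree`.
#' @export
evidenceCounts <- function(net) {
  U <- mldMatrix(net, "all")
  nL <- attr(U, "nLnc")
  Uml <- U[, seq_len(nL), drop = FALSE]
  Umd <- U[, -seq_len(nL), drop = FALSE]
  Y <- matrix(0L, length(net@lncRNAs), length(net@diseases),
              dimnames = list(net@lncRNAs, net@diseases))
  eld <- net@edges[net@edges$layer == "ld", , drop = FALSE]
  if (nrow(eld)) Y[cbind(eld$from, eld$to)] <- 1L
  nPlus <- rowSums((Uml %*% Y) * Umd)
  nl <- rowSums(Uml)
  nd <- rowSums(Umd)
  data.frame(miRNA = rownames(U), nLnc = nl, nDis = nd, nPlus = nPlus,
             nMinus = nl * nd - nPlus, degree = nl + nd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Naive Bayes raw score for a single pair
#'
#' Each common-neighbour miRNA contributes one factor
#' `odds^-1 * (nPlus+1)/(nMinus+1)` (Laplace-smoothed evidence ratio);
#' for recommended common neighbours the evidence ratio is raised to the
#' decay factor `alpha`, down-weighting evidence carried by recommended
#' edges. The full score is the prior odds times the product of all
#' factors; with no common neighbours it reduces to the prior odds.
#'
#' @param partition list with `cn1`, `cn2` from [neighborPartition()].
#' @param evidence data.frame from [evidenceCounts()].
#' @param priors list from [computePriors()].
#' @param alpha decay factor in `(0, 1]`.
#' @return raw score `S > 0`.
#' @export
pairScore <- function(partition, evidence, priors, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  ev <- evidence[match(c(partition$cn1, partition$cn2), evidence$miRNA), ,
                 drop = FALSE]
  if (anyNA(ev$miRNA)) stop("evidence missing for some common neighbours")
  ratio <- (ev$nPlus + 1) / (ev$nMinus + 1)
  n1 <- length(partition$cn1)
  expo <- c(rep(1, n1), rep(alpha, nrow(ev) - n1))
  priors$odds * prod(ratio^expo / priors$odds)
}

#' Degree-normalised score
#'
#' `S' = log(S) / prod(k_m)` over the degrees of all common-neighbour
#' miRNAs in the updated network; the empty-neighbourhood denominator is
#' 1. Note that when `S < 1` the logarithm is negative, so a larger
#' degree product moves the score towards zero from below rather than
#' penalising it; scores are intended for ranking only.
#'
#' @param S raw score (> 0).
#' @param degrees degrees of the common-neighbour miRNAs (possibly empty).
#' @param logBase logarithm base (default natural).
#' @return normalised score `S'`.
#' @export
normalizeScore <- function(S, degrees = numeric(), logBase = exp(1)) {
  stopifnot(S > 0)
  if (length(degrees) && any(degrees <= 0)) {
    stop("common-neighbour degrees must be positive")
  }
  denom <- if (length(degrees)) prod(degrees) else 1
  log(S, base = logBase) / denom
}

#' Score every lncRNA-disease pair
#'
#' Vectorised sweep of [pairScore()] and [normalizeScore()] over the full
#' lncRNA x disease grid, computed in log space with matrix
#' cross-products. Pairs with no common neighbours score the prior odds
#' (raw) and its logarithm (normalised).
#'
#' @param net updated [TripartiteNetwork-class] containing the known
#'   `ld` edges.
#' @param alpha decay factor in `(0, 1]`.
#' @param logBase logarithm base for the normalisation.
#' @param priors optional precomputed priors; defaults to the priors of
#'   `net`'s own `ld` edges.
#' @return a [ScoreResult-class].
#' @export
scoreAllPairs <- function(net, alpha = 0.05, logBase = exp(1),
                          priors = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (is.null(priors)) priors <- .priorsFromNetwork(net)
  U <- mldMatrix(net, "all")
  O <- mldMatrix(net, "original")
  nL <- attr(U, "nLnc")
  iL <- seq_len(nL)
  Uml <- U[, iL, drop = FALSE]; Umd <- U[, -iL, drop = FALSE]
  Oml <- O[, iL, drop = FALSE]; Omd <- O[, -iL, drop = FALSE]

  ev <- evidenceCounts(net)
  logr <- log((ev$nPlus + 1) / (ev$nMinus + 1))
  logk <- ifelse(ev$degree > 0, log(ev$degree), 0)
  lphi <- log(priors$odds)

  n1 <- crossprod(Oml, Omd)              # |CN1| per pair
  nAll <- crossprod(Uml, Umd)            # |CN1 u CN2| per pair
  s1 <- crossprod(Oml, Omd * logr)       # sum log ratio over CN1
  sAll <- crossprod(Uml, Umd * logr)
  sk <- crossprod(Uml, Umd * logk)       # sum log degree over all CN

  logS <- lphi - nAll * lphi + s1 + alpha * (sAll - s1)
  normalized <- (logS / log(logBase)) * exp(-sk)
  new("ScoreResult", raw = exp(logS), normalized = unclass(normalized),
      alpha = alpha, logBase = logBase)
}
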