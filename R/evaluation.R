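#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds, accumulating true and
#' false positive rates, and integrates the curve with the trapezoidal
#' rule. Tied scores are grouped at a single threshold, which makes the
#' trapezoidal AUC identical to the rank-statistic (concordance) AUC.
#'
#' @param scores numeric prediction scores (higher = more likely
#'   positive).
#' @param labels 0/1 (or logical) true labels; both classes must be
#'   present.
#' @return list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # group ties at one threshold
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = s[last], fpr = fpr, tpr = tpr, auc = auc)
}

# miRNA-degree baseline: score(l, d) = (# miRNA neighbours of l) *
# (# miRNA neighbours of d) in the updated network
.degreeScores <- function(net) {
  U <- mldMatrix(net, "all")
  nL <- attr(U, "nLnc")
  degL <- colSums(U[, seq_len(nL), drop = FALSE])
  degD <- colSums(U[, -seq_len(nL), drop = FALSE])
  outer(degL, degD)
}

# score matrix for one training ld table, given a fixed CF-updated
# network skeleton (ld edges swapped in)
.scoreWithLd <- function(cfNet, ldTrain, alpha, logBase, SD = NULL,
                         scorer = "model") {
  e <- cfNet@edges[cfNet@edges$layer != "ld", , drop = FALSE]
  if (nrow(ldTrain)) {
    e <- rbind(e, data.frame(from = ldTrain$source, to = ldTrain$target,
                             layer = "ld", provenance = "original",
                             stringsAsFactors = FALSE))
  }
  net <- cfNet
  net@edges <- e
  if (scorer == "degree") return(.degreeScores(net))
  sc <- scoreAllPairs(net, alpha = alpha, logBase = logBase)
  if (is.null(SD)) normScores(sc) else combineScores(sc, SD)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' Each known lncRNA-disease association is held out in turn; the naive
#' Bayes stage is refit on the remaining associations and the held-out
#' lncRNA is ranked among all candidate lncRNAs for its disease
#' (candidates are the lncRNAs without a training association to that
#' disease). The collaborative-filtering stage consumes only the
#' miRNA-lncRNA and miRNA-disease layers, which the folds never alter,
#' so it is computed once. Fold scores are pooled (held-out pairs as
#' positives, other candidates as negatives) into one ROC.
#'
#' @param ml,md,ld association tables (already harmonized, or raw -- they
#'   are harmonized internally).
#' @param dag optional [DiseaseDAG-class]; when supplied the semantic
#'   stage multiplies the score matrix by the disease similarity matrix.
#' @param alpha decay factor in `(0, 1]`.
#' @param k collaborative-filtering neighbourhood, see
#'   [recommenderScores()].
#' @param delta semantic contribution factor.
#' @param logBase logarithm base of the score normalisation.
#' @param scorer `"model"` for the naive Bayes pipeline or `"degree"`
#'   for the miRNA-degree baseline.
#' @return list with `folds` (data.frame: lncRNA, disease, score, rank,
#'   nCandidates), `roc`, `auc`, `aucPerDisease`.
#' @export
runLoocv <- function(ml, md, ld, dag = NULL, alpha = 0.05, k = "all",
                     delta = 0.5, logBase = exp(1), scorer = c("model", "degree")) {
  scorer <- match.arg(scorer)
  tabs <- harmonizeTables(md, ml, ld)
  if (nrow(tabs$ld) < 2) stop("need at least 2 known lncRNA-disease associations")
  net0 <- buildTripartite(tabs$ml, tabs$md, tabs$ld)
  cf <- applyCollaborativeFiltering(
    buildTripartite(tabs$ml, tabs$md), k = k)
  cfNet <- cf$network
  # carry node sets from the full network (ld may add isolated nodes)
  cfNet@lncRNAs <- net0@lncRNAs
  cfNet@diseases <- net0@diseases
  SD <- if (!is.null(dag)) diseaseSimilarity(dag, net0@diseases, delta)

  ldTab <- tabs$ld
  ldKey <- paste(ldTab$source, ldTab$target)
  folds <- vector("list", nrow(ldTab))
  pooledScores <- list()
  pooledLabels <- list()
  for (i in seq_len(nrow(ldTab))) {
    l <- ldTab$source[i]
    d <- ldTab$target[i]
    train <- ldTab[-i, , drop = FALSE]
    sc <- tryCatch(
      .scoreWithLd(cfNet, train, alpha, logBase, SD, scorer),
      error = function(e) NULL
    )
    if (is.null(sc)) {
      warning(sprintf("fold (%s, %s) skipped: no usable training signal", l, d))
      next
    }
    knownForD <- train$source[train$target == d]
    candidates <- setdiff(rownames(sc), knownForD)
    s <- sc[candidates, d]
    rk <- rank(-s, ties.method = "average")[match(l, candidates)]
    folds[[i]] <- data.frame(lncRNA = l, disease = d, score = sc[l, d],
                             rank = rk, nCandidates = length(candidates),
                             stringsAsFactors = FALSE)
    pooledScores[[i]] <- s
    pooledLabels[[i]] <- as.integer(candidates == l)
  }
  folds <- do.call(rbind, folds)
  roc <- rocAuc(unlist(pooledScores), unlist(pooledLabels))
  foldAuc <- ifelse(folds$nCandidates > 1,
                    1 - (folds$rank - 1) / (folds$nCandidates - 1), NA_real_)
  perDis <- vapply(split(foldAuc, folds$disease),
                   function(r) mean(r, na.rm = TRUE), numeric(1))
  list(folds = folds, roc = roc, auc = roc$auc, aucPerDisease = perDis)
}

#' Precision, recall and F1 among the top-k predictions
#'
#' @param ranked character vector of predicted pair identifiers in
#'   decreasing score order.
#' @param positives character vector of held-out positive identifiers.
#' @param k cutoff (>= 1).
#' @return list with `k`, `precision`, `recall`, `f1`.
#' @export
f1AtK <- function(ranked, positives, k) {
  stopifnot(k >= 1)
  if (!length(positives)) stop("no positives in the test split")
  hits <- sum(utils::head(ranked, k) %in% positives)
  precision <- hits / k
  recall <- hits / length(positives)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(k = k, precision = precision, recall = recall, f1 = f1)
}

#' Top-k F1 under a seeded 80/20 association split
#'
#' Randomly assigns the stated fraction of known lncRNA-disease
#' associations to training, fits the pipeline on the training set,
#' ranks all pairs outside the training set pooled across diseases, and
#' evaluates F1 at each requested cutoff against the held-out
#' associations.
#'
#' @inheritParams runLoocv
#' @param ks integer vector of cutoffs.
#' @param trainFrac fraction of associations used for training.
#' @param seed integer seed controlling the split.
#' @return data.frame with one row per cutoff (`k`, `precision`,
#'   `recall`, `f1`) and attribute `nTest`.
#' @export
evaluateSplit <- function(ml, md, ld, dag = NULL, alpha = 0.05, k = "all",
                          delta = 0.5, logBase = exp(1),
                          ks = c(5, 10, 15, 20), trainFrac = 0.8, seed = 1) {
  tabs <- harmonizeTables(md, ml, ld)
  n <- nrow(tabs$ld)
  if (n < 5) stop("too few associations to split")
  idx <- withr::with_seed(seed, sample.int(n, size = max(1, round(trainFrac * n))))
  train <- tabs$ld[idx, , drop = FALSE]
  test <- tabs$ld[-idx, , drop = FALSE]
  if (!nrow(test)) stop("no positives in the test split")

  net0 <- buildTripartite(tabs$ml, tabs$md, tabs$ld)
  cf <- applyCollaborativeFiltering(buildTripartite(tabs$ml, tabs$md), k = k)
  cfNet <- cf$network
  cfNet@lncRNAs <- net0@lncRNAs
  cfNet@diseases <- net0@diseases
  SD <- if (!is.null(dag)) diseaseSimilarity(dag, net0@diseases, delta)
  sc <- .scoreWithLd(cfNet, train, alpha, logBase, SD)

  pairId <- function(l, d) paste(l, d, sep = "\r")
  trainId <- pairId(train$source, train$target)
  grid <- expand.grid(l = rownames(sc), d = colnames(sc),
                      stringsAsFactors = FALSE)
  grid$id <- pairId(grid$l, grid$d)
  grid <- grid[!(grid$id %in% trainId), , drop = FALSE]
  grid$score <- sc[cbind(grid$l, grid$d)]
  ranked <- grid$id[order(-grid$score)]
  positives <- pairId(test$source, test$target)

  out <- do.call(rbind, lapply(ks, function(kk) {
    as.data.frame(f1AtK(ranked, positives, kk))
  }))
  attr(out, "nTest") <- nrow(test)
  out
}

#' Paired t-test on two score series
#'
#' Classical paired t-test with `n - 1` degrees of freedom and a
#' two-sided p-value. Identically zero differences return `t = 0`,
#' `p = 1` by convention; nonzero constant differences (zero variance)
#' are an error.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 paired observations")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(statistic = 0, df = length(x) - 1, p.value = 1))
    }
    stop("zero-variance differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}
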