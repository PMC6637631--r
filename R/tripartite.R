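#' Build the original tripartite network
#'
#' Assembles the heterogeneous lncRNA-miRNA-disease network from the
#' miRNA-lncRNA, miRNA-disease and (optionally) lncRNA-disease
#' association tables. All edges are flagged `original`. Labels differing
#' only in case/whitespace are unified to their first-seen spelling.
#'
#' @param ml miRNA-lncRNA association table.
#' @param md miRNA-disease association table.
#' @param ld optional lncRNA-disease association table.
#' @return a [TripartiteNetwork-class] object.
#' @export
buildTripartite <- function(ml, md, ld = NULL) {
  canon <- local({
    all <- c(ml$source, ml$target, md$source, md$target,
             if (!is.null(ld)) c(ld$source, ld$target))
    first <- !duplicated(.key(all))
    stats::setNames(all[first], .key(all)[first])
  })
  cn <- function(x) unname(canon[.key(x)])

  mirnas <- sort(unique(cn(c(ml$source, md$source))))
  lncs <- sort(unique(cn(c(ml$target, if (!is.null(ld)) ld$source))))
  dis <- sort(unique(cn(c(md$target, if (!is.null(ld)) ld$target))))

  layerDf <- function(tab, layer) {
    if (is.null(tab) || !nrow(tab)) return(NULL)
    data.frame(from = cn(tab$source), to = cn(tab$target),
               layer = rep(layer, nrow(tab)), stringsAsFactors = FALSE)
  }
  e <- rbind(layerDf(ml, "ml"), layerDf(md, "md"), layerDf(ld, "ld"))
  if (is.null(e)) {
    e <- data.frame(from = character(), to = character(),
                    layer = character(), stringsAsFactors = FALSE)
  }
  e <- e[!duplicated(e), , drop = FALSE]
  e$provenance <- "original"
  rownames(e) <- NULL
  new("TripartiteNetwork", lncRNAs = lncs, miRNAs = mirnas,
      diseases = dis, edges = e)
}

#' Spliced miRNA x (lncRNA, disease) adjacency matrix
#'
#' Returns the binary adjacency matrix whose rows are miRNAs and whose
#' columns are all lncRNAs followed by all diseases (the two "user"
#' blocks of the recommender). The lncRNA block width is stored in
#' attribute `nLnc`.
#'
#' @param net a [TripartiteNetwork-class].
#' @param provenance `"original"` for the original network, `"all"` to
#'   include collaborative-filtering recommended edges.
#' @return binary matrix with dimnames; attribute `nLnc` gives the
#'   column index where the disease block starts minus one.
#' @export
mldMatrix <- function(net, provenance = c("original", "all")) {
  provenance <- match.arg(provenance)
  keep <- if (provenance == "all") .PROVENANCE else "original"
  m <- matrix(0L, length(net@miRNAs),
              length(net@lncRNAs) + length(net@diseases),
              dimnames = list(net@miRNAs, c(net@lncRNAs, net@diseases)))
  e <- net@edges
  e <- e[e$layer %in% c("ml", "md") & e$provenance %in% keep, , drop = FALSE]
  if (nrow(e)) m[cbind(e$from, e$to)] <- 1L
  attr(m, "nLnc") <- length(net@lncRNAs)
  m
}

#' miRNA co-occurrence matrix
#'
#' Binary, symmetric miRNA x miRNA matrix with entry 1 iff the two
#' miRNAs share at least one common neighbouring lncRNA or disease in the
#' network; the diagonal is 0.
#'
#' @param R0 spliced adjacency matrix from [mldMatrix()].
#' @return binary symmetric matrix with zero diagonal.
#' @export
cooccurrence <- function(R0) {
  stopifnot(nrow(R0) > 0)
  co <- (tcrossprod(R0) > 0) * 1L
  diag(co) <- 0L
  co
}

#' Normalised miRNA-miRNA similarity
#'
#' Cosine-style similarity between the neighbour sets of two miRNAs:
#' `|N(mk) ∩ N(mr)| / sqrt(|N(mk)| * |N(mr)|)`, where neighbours are the
#' lncRNAs and diseases adjacent in the original network. The diagonal is
#' forced to 0 and any pair involving a zero-degree miRNA scores 0.
#'
#' @param R0 spliced adjacency matrix from [mldMatrix()].
#' @return symmetric matrix with entries in `[0, 1]` and zero diagonal.
#' @export
mirnaSimilarity <- function(R0) {
  stopifnot(nrow(R0) > 0)
  inter <- tcrossprod(R0)
  deg <- rowSums(R0)
  denom <- sqrt(outer(deg, deg))
  sim <- ifelse(denom > 0, inter / denom, 0)
  diag(sim) <- 0
  sim
}

#' Recommender score matrix
#'
#' Scores every (miRNA, user) cell of the spliced adjacency by item-based
#' collaborative filtering. With `k = "all"` this is the matrix product
#' of the similarity matrix with the adjacency (the similarity diagonal
#' is zero, so a miRNA never recommends itself). With finite `k`, the
#' score of miRNA `t` for a user sums similarity only over miRNAs that
#' are both known neighbours of the user and among the `k` miRNAs most
#' similar to `t` (ties broken by row order).
#'
#' @param sim similarity matrix from [mirnaSimilarity()].
#' @param R0 spliced adjacency matrix from [mldMatrix()].
#' @param k `"all"` or a positive integer neighbourhood size.
#' @return real matrix aligned with `R0` (non-negative entries).
#' @export
recommenderScores <- function(sim, R0, k = "all") {
  stopifnot(nrow(sim) == ncol(sim), nrow(sim) == nrow(R0))
  if (identical(k, "all")) {
    out <- sim %*% R0
  } else {
    k <- as.integer(k)
    if (is.na(k) || k <= 0) stop("k must be a positive integer or \"all\"")
    m <- nrow(sim)
    out <- matrix(0, m, ncol(R0), dimnames = dimnames(R0))
    for (t in seq_len(m)) {
      top <- order(sim[t, ], decreasing = TRUE)[seq_len(min(k, m - 1))]
      for (u in seq_len(ncol(R0))) {
        nbr <- intersect(top, which(R0[, u] == 1))
        out[t, u] <- sum(sim[t, nbr])
      }
    }
  }
  attr(out, "nLnc") <- attr(R0, "nLnc")
  out
}

#' Mean-threshold miRNA recommendations
#'
#' For each user (lncRNA or disease column) with at least one known
#' miRNA association, the threshold is the mean recommender score over
#' that user's known-associated miRNAs; every miRNA with no existing
#' edge to the user and a score strictly above the threshold is
#' recommended. Users with no known association are skipped.
#'
#' @param R1 recommender matrix from [recommenderScores()].
#' @param R0 aligned binary adjacency from [mldMatrix()].
#' @return data.frame with columns `miRNA`, `user`, `userRole`
#'   (`"lncRNA"` or `"disease"`), `score`, `threshold`.
#' @export
recommendEdges <- function(R1, R0) {
  stopifnot(identical(dim(R1), dim(R0)))
  nLnc <- attr(R0, "nLnc")
  out <- vector("list", ncol(R0))
  for (u in seq_len(ncol(R0))) {
    known <- R0[, u] == 1
    if (!any(known)) next
    pbar <- mean(R1[known, u])
    hit <- !known & R1[, u] > pbar
    if (!any(hit)) next
    out[[u]] <- data.frame(
      miRNA = rownames(R0)[hit],
      user = colnames(R0)[u],
      userRole = if (!is.null(nLnc) && u <= nLnc) "lncRNA" else "disease",
      score = R1[hit, u],
      threshold = pbar,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(miRNA = character(), user = character(),
                      userRole = character(), score = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Add recommended edges to the network
#'
#' Returns the updated network with the additions flagged
#' `recommended`; original edges are untouched. Adding an edge that
#' already exists (either original or previously recommended) is an
#' error.
#'
#' @param net a [TripartiteNetwork-class].
#' @param additions data.frame with columns `miRNA`, `user` (output of
#'   [recommendEdges()] works directly).
#' @return updated [TripartiteNetwork-class].
#' @export
addRecommendedEdges <- function(net, additions) {
  if (!nrow(additions)) return(net)
  if (!all(additions$miRNA %in% net@miRNAs)) stop("unknown miRNA in additions")
  layer <- ifelse(additions$user %in% net@lncRNAs, "ml",
                  ifelse(additions$user %in% net@diseases, "md", NA))
  if (anyNA(layer)) stop("unknown user node in additions")
  newe <- data.frame(from = additions$miRNA, to = additions$user,
                     layer = layer, provenance = "recommended",
                     stringsAsFactors = FALSE)
  keyOld <- paste(net@edges$layer, net@edges$from, net@edges$to)
  keyNew <- paste(newe$layer, newe$from, newe$to)
  if (any(keyNew %in% keyOld)) {
    stop("addition duplicates an existing edge: ",
         paste(keyNew[keyNew %in% keyOld], collapse = "; "))
  }
  net@edges <- rbind(net@edges, newe)
  rownames(net@edges) <- NULL
  validObject(net)
  net
}

#' Run the collaborative-filtering stage
#'
#' Convenience wrapper: builds the spliced adjacency, the co-occurrence
#' and similarity matrices, the recommender matrix, applies the
#' mean-threshold rule and returns the updated network together with all
#' intermediates.
#'
#' @param net original [TripartiteNetwork-class].
#' @param k recommender neighbourhood size, see [recommenderScores()].
#' @return list with `network` (updated), `recommendations`,
#'   `similarity`, `cooccurrence`, `recommender`, `adjacency`.
#' @export
applyCollaborativeFiltering <- function(net, k = "all") {
  R0 <- mldMatrix(net, "original")
  co <- cooccurrence(R0)
  sim <- mirnaSimilarity(R0)
  R1 <- recommenderScores(sim, R0, k = k)
  rec <- recommendEdges(R1, R0)
  list(
    network = addRecommendedEdges(net, rec),
    recommendations = rec,
    similarity = sim,
    cooccurrence = co,
    recommender = R1,
    adjacency = R0
  )
}
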