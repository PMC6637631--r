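#' Parse a disease ontology DAG from (child, parent) links
#'
#' @param x path to a two-column TSV/CSV of (child, parent) records, or
#'   a data.frame with those two columns.
#' @return a [DiseaseDAG-class]; errors on self-parenting or cycles.
#' @export
parseDiseaseDAG <- function(x) {
  if (is.character(x) && length(x) == 1) {
    tab <- readAssociationTable(x, "lncRNA-disease", quiet = TRUE)
    df <- data.frame(child = tab$source, parent = tab$target,
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("child", "parent")
    df <- df[, c("child", "parent")]
    df <- df[!duplicated(df), , drop = FALSE]
  }
  df$child <- trimws(df$child)
  df$parent <- trimws(df$parent)
  nodes <- sort(unique(c(df$child, df$parent)))
  rownames(df) <- NULL
  new("DiseaseDAG", nodes = nodes, parents = df)
}

# ancestor closure T(d): d plus everything reachable via parent links
.ancestorClosure <- function(dag, d) {
  seen <- d
  frontier <- d
  p <- dag@parents
  while (length(frontier)) {
    nxt <- unique(p$parent[p$child %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Semantic contribution profile of a disease
#'
#' Within the sub-DAG induced by a disease and its ancestors, the
#' disease itself contributes 1 and every ancestor `t` contributes
#' `max(delta * D(ct))` over its children `ct` inside the sub-DAG
#' (the standard descriptor-contribution measure, with semantic
#' contribution factor `delta`). The semantic value `DV` is the sum of
#' all contributions.
#'
#' @param dag a [DiseaseDAG-class].
#' @param d disease label (must be a node of `dag`).
#' @param delta semantic contribution factor in `(0, 1)`.
#' @return named numeric vector of contributions with attribute `DV`.
#' @export
semanticProfile <- function(dag, d, delta = 0.5) {
  if (!(d %in% dag@nodes)) stop("disease not in DAG: ", d)
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  anc <- .ancestorClosure(dag, d)
  p <- dag@parents[dag@parents$child %in% anc &
                     dag@parents$parent %in% anc, , drop = FALSE]
  memo <- new.env(parent = emptyenv())
  contrib <- function(t) {
    if (t == d) return(1)
    if (!is.null(memo[[t]])) return(memo[[t]])
    ch <- p$child[p$parent == t]
    val <- max(vapply(ch, function(ct) delta * contrib(ct), numeric(1)))
    memo[[t]] <- val
    val
  }
  out <- vapply(anc, contrib, numeric(1))
  names(out) <- anc
  attr(out, "DV") <- sum(out)
  out
}

#' Semantic similarity of two disease profiles
#'
#' `SD = sum over shared ancestors of (D_i(t) + D_j(t)) / (DV_i + DV_j)`,
#' always in `[0, 1]` and equal to 1 for identical profiles.
#'
#' @param profileI,profileJ profiles from [semanticProfile()] built on
#'   the same DAG with the same `delta`.
#' @return similarity value in `[0, 1]`.
#' @export
semanticSimilarity <- function(profileI, profileJ) {
  shared <- intersect(names(profileI), names(profileJ))
  num <- sum(profileI[shared]) + sum(profileJ[shared])
  num / (attr(profileI, "DV") + attr(profileJ, "DV"))
}

#' Pairwise disease semantic similarity matrix
#'
#' Computes the full similarity matrix for a set of diseases. Diseases
#' absent from the DAG fall back to identity similarity (1 with
#' themselves, 0 with everything else), so the semantic stage degrades
#' per-disease rather than failing.
#'
#' @param dag a [DiseaseDAG-class].
#' @param diseaseLabels character vector of diseases (matrix order).
#' @param delta semantic contribution factor in `(0, 1)`.
#' @return symmetric matrix with unit diagonal and entries in `[0, 1]`.
#' @export
diseaseSimilarity <- function(dag, diseaseLabels, delta = 0.5) {
  n <- length(diseaseLabels)
  SD <- diag(1, n)
  dimnames(SD) <- list(diseaseLabels, diseaseLabels)
  inDag <- diseaseLabels[diseaseLabels %in% dag@nodes]
  if (length(inDag) >= 2) {
    profs <- lapply(inDag, semanticProfile, dag = dag, delta = delta)
    names(profs) <- inDag
    for (i in seq_along(inDag)[-length(inDag)]) {
      for (j in seq((i + 1), length(inDag))) {
        s <- semanticSimilarity(profs[[i]], profs[[j]])
        SD[inDag[i], inDag[j]] <- s
        SD[inDag[j], inDag[i]] <- s
      }
    }
  }
  SD
}

#' Combine normalised scores with disease semantic similarity
#'
#' Final prediction matrix: the matrix product of the normalised score
#' matrix (lncRNA x disease) with the disease similarity matrix
#' (disease x disease), propagating a lncRNA's scores across
#' semantically similar diseases. With an identity similarity matrix the
#' scores are returned unchanged.
#'
#' @param scores a [ScoreResult-class] or a plain lncRNA x disease
#'   matrix of normalised scores.
#' @param SD disease similarity matrix from [diseaseSimilarity()].
#' @return lncRNA x disease matrix of final scores.
#' @export
combineScores <- function(scores, SD) {
  S <- if (is(scores, "ScoreResult")) normScores(scores) else scores
  if (ncol(S) != nrow(SD)) stop("disease dimensions do not match")
  if (!is.null(colnames(S)) && !is.null(rownames(SD))) {
    if (!all(colnames(S) %in% rownames(SD))) {
      stop("SD is missing diseases present in the score matrix")
    }
    SD <- SD[colnames(S), colnames(S), drop = FALSE]
  }
  S %*% SD
}
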