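#' @import methods
NULL

.EDGE_LAYERS <- c("ml", "md", "ld")
.PROVENANCE <- c("original", "recommended")

#' Tripartite lncRNA-miRNA-disease network
#'
#' Container for the heterogeneous network on which association prediction
#' runs. Nodes fall into three disjoint roles (lncRNA, miRNA, disease) and
#' edges connect a miRNA to a lncRNA (`ml`), a miRNA to a disease (`md`), or
#' a lncRNA to a disease (`ld`). Every edge carries a provenance flag:
#' `"original"` for edges taken from the input association tables, or
#' `"recommended"` for edges added by the collaborative-filtering stage.
#' Within-role edges are forbidden and `ld` edges are always original (the
#' recommender only proposes miRNA neighbours).
#'
#' @slot lncRNAs character vector of lncRNA labels (sorted, unique).
#' @slot miRNAs character vector of miRNA labels (sorted, unique).
#' @slot diseases character vector of disease labels (sorted, unique).
#' @slot edges data.frame with columns `from`, `to`, `layer`
#'   (one of `"ml"`, `"md"`, `"ld"`) and `provenance`. For `ml`/`md`
#'   edges `from` is the miRNA; for `ld` edges `from` is the lncRNA.
#'
#' @seealso [buildTripartite()], [applyCollaborativeFiltering()]
#' @export
setClass("TripartiteNetwork",
  slots = c(
    lncRNAs = "character",
    miRNAs = "character",
    diseases = "character",
    edges = "data.frame"
  )
)

setValidity("TripartiteNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  need <- c("from", "to", "layer", "provenance")
  if (!all(need %in% names(e))) {
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(object@lncRNAs) || anyDuplicated(object@miRNAs) ||
      anyDuplicated(object@diseases)) {
    msgs <- c(msgs, "node labels must be unique within each role")
  }
  if (length(intersect(object@miRNAs, object@lncRNAs)) ||
      length(intersect(object@miRNAs, object@diseases)) ||
      length(intersect(object@lncRNAs, object@diseases))) {
    msgs <- c(msgs, "node roles must be disjoint")
  }
  if (nrow(e)) {
    if (!all(e$layer %in% .EDGE_LAYERS)) {
      msgs <- c(msgs, "edge layer must be one of ml, md, ld")
    }
    if (!all(e$provenance %in% .PROVENANCE)) {
      msgs <- c(msgs, "edge provenance must be original or recommended")
    }
    if (any(e$layer == "ld" & e$provenance != "original")) {
      msgs <- c(msgs, "ld edges must be original")
    }
    ok <- (e$layer == "ml" & e$from %in% object@miRNAs & e$to %in% object@lncRNAs) |
      (e$layer == "md" & e$from %in% object@miRNAs & e$to %in% object@diseases) |
      (e$layer == "ld" & e$from %in% object@lncRNAs & e$to %in% object@diseases)
    if (!all(ok)) msgs <- c(msgs, "edge endpoints must match their layer's roles")
    if (anyDuplicated(e[, c("layer", "from", "to")])) {
      msgs <- c(msgs, "duplicate edges are not allowed")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Disease ontology DAG
#'
#' A directed acyclic graph of disease descriptors (e.g. extracted from
#' MeSH), stored as (child, parent) links. Used to compute semantic value
#' profiles and pairwise disease semantic similarity.
#'
#' @slot nodes character vector of descriptor labels.
#' @slot parents data.frame with columns `child`, `parent`.
#'
#' @seealso [parseDiseaseDAG()], [diseaseSimilarity()]
#' @export
setClass("DiseaseDAG",
  slots = c(nodes = "character", parents = "data.frame")
)

setValidity("DiseaseDAG", function(object) {
  p <- object@parents
  if (!all(c("child", "parent") %in% names(p))) {
    return("parents must have columns child, parent")
  }
  if (nrow(p)) {
    if (any(p$child == p$parent)) return("self-parenting link detected")
    if (!all(c(p$child, p$parent) %in% object@nodes)) {
      return("parent links reference unknown nodes")
    }
    if (anyDuplicated(p)) return("duplicate parent links")
    g <- igraph::graph_from_data_frame(p, directed = TRUE,
                                       vertices = object@nodes)
    if (!igraph::is_dag(g)) return("cycle detected: structure is not a DAG")
  }
  TRUE
})

#' Naive Bayes score matrices for all lncRNA-disease pairs
#'
#' Holds the raw odds-form score S and the degree-normalised score
#' S' = log(S) / prod(degrees of common neighbours) for every
#' lncRNA (row) x disease (column) pair, together with the decay factor
#' and logarithm base used.
#'
#' @slot raw numeric matrix of raw scores S (strictly positive).
#' @slot normalized numeric matrix of normalised scores S'.
#' @slot alpha decay factor applied to recommended-neighbour evidence.
#' @slot logBase base of the logarithm used in the normalisation.
#'
#' @seealso [scoreAllPairs()], [combineScores()]
#' @export
setClass("ScoreResult",
  slots = c(
    raw = "matrix",
    normalized = "matrix",
    alpha = "numeric",
    logBase = "numeric"
  )
)

setValidity("ScoreResult", function(object) {
  if (!identical(dim(object@raw), dim(object@normalized))) {
    return("raw and normalized matrices must share dimensions")
  }
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha > 1) {
    return("alpha must be a single value in (0, 1]")
  }
  TRUE
})
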