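#' @rdname TripartiteNetwork-class
#' @param x a `TripartiteNetwork`.
#' @export
setGeneric("lncRNAs", function(x) standardGeneric("lncRNAs"))

#' @rdname TripartiteNetwork-class
#' @export
setGeneric("miRNAs", function(x) standardGeneric("miRNAs"))

#' @rdname TripartiteNetwork-class
#' @export
setGeneric("diseases", function(x) standardGeneric("diseases"))

#' @rdname TripartiteNetwork-class
#' @param layer optional filter: one of `"ml"`, `"md"`, `"ld"`.
#' @param provenance optional filter: `"original"` or `"recommended"`.
#' @export
setGeneric("edges", function(x, layer = NULL, provenance = NULL)
  standardGeneric("edges"))

#' @rdname ScoreResult-class
#' @param x a `ScoreResult`.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname ScoreResult-class
#' @export
setGeneric("normScores", function(x) standardGeneric("normScores"))

#' @rdname TripartiteNetwork-class
#' @export
setMethod("lncRNAs", "TripartiteNetwork", function(x) x@lncRNAs)

#' @rdname TripartiteNetwork-class
#' @export
setMethod("miRNAs", "TripartiteNetwork", function(x) x@miRNAs)

#' @rdname TripartiteNetwork-class
#' @export
setMethod("diseases", "TripartiteNetwork", function(x) x@diseases)

#' @rdname TripartiteNetwork-class
#' @export
setMethod("edges", "TripartiteNetwork", function(x, layer = NULL,
                                                 provenance = NULL) {
  e <- x@edges
  if (!is.null(layer)) e <- e[e$layer %in% layer, , drop = FALSE]
  if (!is.null(provenance)) e <- e[e$provenance %in% provenance, , drop = FALSE]
  rownames(e) <- NULL
  e
})

#' @rdname ScoreResult-class
#' @export
setMethod("rawScores", "ScoreResult", function(x) x@raw)

#' @rdname ScoreResult-class
#' @export
setMethod("normScores", "ScoreResult", function(x) x@normalized)

setMethod("show", "TripartiteNetwork", function(object) {
  e <- object@edges
  cat(sprintf(
    "TripartiteNetwork: %d lncRNAs, %d miRNAs, %d diseases\n",
    length(object@lncRNAs), length(object@miRNAs), length(object@diseases)
  ))
  for (ly in .EDGE_LAYERS) {
    n <- sum(e$layer == ly)
    nr <- sum(e$layer == ly & e$provenance == "recommended")
    cat(sprintf("  %s edges: %d (%d recommended)\n", ly, n, nr))
  }
  invisible(object)
})

setMethod("show", "DiseaseDAG", function(object) {
  cat(sprintf("DiseaseDAG: %d nodes, %d parent links\n",
              length(object@nodes), nrow(object@parents)))
  invisible(object)
})

setMethod("show", "ScoreResult", function(object) {
  cat(sprintf(
    "ScoreResult: %d lncRNAs x %d diseases (alpha = %g, log base = %g)\n",
    nrow(object@raw), ncol(object@raw), object@alpha, object@logBase
  ))
  invisible(object)
})
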