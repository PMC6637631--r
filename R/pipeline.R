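.asTable <- function(x, kind) {
  if (is.character(x) && length(x) == 1) {
    readAssociationTable(x, kind, quiet = TRUE)
  } else {
    associationTable(x[[1]], x[[2]], kind)
  }
}

#' Run the full prediction pipeline
#'
#' Wires the stages end to end: read/harmonize the three association
#' tables, build the tripartite network, densify it with the
#' collaborative-filtering recommendation step, score all lncRNA-disease
#' pairs with the naive Bayes classifier, optionally modulate by disease
#' semantic similarity, and (optionally) evaluate by LOOCV or an 80/20
#' top-k split. When `outDir` is given, the updated network, the score
#' matrices, a ranked pair list and a JSON run report (embedding the
#' exact configuration and seed) are written there.
#'
#' @param ml,md,ld association tables or file paths (`ld` may be `NULL`
#'   when no scoring/evaluation is requested).
#' @param dag optional [DiseaseDAG-class] or path to a (child, parent)
#'   edge list; enables the semantic-similarity stage.
#' @param alias optional alias map ([readAliasMap()]) or path.
#' @param alpha decay factor in `(0, 1]` (default 0.05).
#' @param k collaborative-filtering neighbourhood (`"all"` or a positive
#'   integer).
#' @param delta semantic contribution factor in `(0, 1)`.
#' @param logBase logarithm base of the score normalisation.
#' @param evaluation `"none"`, `"loocv"` or `"split"`.
#' @param seed integer seed for the split evaluation.
#' @param ks cutoffs for the split evaluation.
#' @param outDir optional output directory.
#' @return list with `config`, `tables`, `network` (updated),
#'   `recommendations`, `scores` ([ScoreResult-class] or `NULL`),
#'   `final` (combined matrix or `NULL`), `evaluation`.
#' @export
runPipeline <- function(ml, md, ld = NULL, dag = NULL, alias = NULL,
                        alpha = 0.05, k = "all", delta = 0.5,
                        logBase = exp(1),
                        evaluation = c("none", "loocv", "split"),
                        seed = 1, ks = c(5, 10, 15, 20), outDir = NULL) {
  evaluation <- match.arg(evaluation)
  if (alpha <= 0 || alpha > 1) stop("config error: alpha must be in (0, 1]")
  if (delta <= 0 || delta >= 1) stop("config error: delta must be in (0, 1)")
  if (!identical(k, "all") && (!is.numeric(k) || k < 1)) {
    stop("config error: k must be \"all\" or a positive integer")
  }
  if (is.null(ld) && evaluation != "none") {
    stop("config error: evaluation requires a lncRNA-disease table")
  }
  ml <- .asTable(ml, "miRNA-lncRNA")
  md <- .asTable(md, "miRNA-disease")
  if (!is.null(ld)) ld <- .asTable(ld, "lncRNA-disease")
  if (is.character(alias)) alias <- readAliasMap(alias)
  if (is.character(dag)) dag <- parseDiseaseDAG(dag)

  config <- list(alpha = alpha, k = k, delta = delta, logBase = logBase,
                 semsim = !is.null(dag), evaluation = evaluation,
                 seed = seed)

  if (!is.null(ld)) {
    tabs <- harmonizeTables(md, ml, ld, alias)
  } else {
    tabs <- list(md = .applyAlias(md, alias), ml = .applyAlias(ml, alias),
                 ld = NULL)
  }
  net <- buildTripartite(tabs$ml, tabs$md, tabs$ld)
  message(sprintf("network: %d lncRNAs, %d miRNAs, %d diseases, %d edges",
                  length(net@lncRNAs), length(net@miRNAs),
                  length(net@diseases), nrow(net@edges)))

  cf <- applyCollaborativeFiltering(net, k = k)
  message(sprintf("collaborative filtering added %d recommended edge(s)",
                  nrow(cf$recommendations)))

  scores <- final <- evalResult <- NULL
  if (!is.null(tabs$ld) && nrow(tabs$ld) > 0) {
    scores <- scoreAllPairs(cf$network, alpha = alpha, logBase = logBase)
    if (!is.null(dag)) {
      SD <- diseaseSimilarity(dag, colnames(normScores(scores)), delta)
      final <- combineScores(scores, SD)
    } else {
      final <- normScores(scores)
    }
    if (evaluation == "loocv") {
      evalResult <- runLoocv(tabs$ml, tabs$md, tabs$ld, dag = dag,
                             alpha = alpha, k = k, delta = delta,
                             logBase = logBase)
      message(sprintf("LOOCV AUC: %.4f", evalResult$auc))
    } else if (evaluation == "split") {
      evalResult <- evaluateSplit(tabs$ml, tabs$md, tabs$ld, dag = dag,
                                  alpha = alpha, k = k, delta = delta,
                                  logBase = logBase, ks = ks, seed = seed)
    }
  }

  result <- list(config = config, tables = tabs, network = cf$network,
                 recommendations = cf$recommendations, scores = scores,
                 final = final, evaluation = evalResult)
  if (!is.null(outDir)) .writeArtifacts(result, outDir)
  result
}

.writeArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  e <- result$network@edges
  utils::write.table(e, file.path(outDir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$final)) {
    utils::write.table(result$final, file.path(outDir, "scores.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    grid <- expand.grid(lncRNA = rownames(result$final),
                        disease = colnames(result$final),
                        stringsAsFactors = FALSE)
    grid$score <- result$final[cbind(grid$lncRNA, grid$disease)]
    grid <- grid[order(-grid$score), , drop = FALSE]
    utils::write.table(grid, file.path(outDir, "ranked_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    config = result$config,
    counts = if (!is.null(result$tables$ld)) tableSummary(result$tables),
    nRecommended = nrow(result$recommendations),
    auc = if (!is.null(result$evaluation$auc)) result$evaluation$auc,
    f1 = if (is.data.frame(result$evaluation)) result$evaluation
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outDir)
}
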