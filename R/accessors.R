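## Generics, accessors and show methods for the core classes.

#' Node identifiers of an object
#' @param x A CentralityMatrix, SimilarityScores, RankingTable or
#'   ClusterLabels object.
#' @return Character vector of node identifiers.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Measure labels of an object
#' @param x A CentralityMatrix or ImportanceReport.
#' @return Character vector of centrality measure labels.
#' @export
setGeneric("measureNames", function(x) standardGeneric("measureNames"))

#' Seed members
#' @param x A SeedSet.
#' @return Character vector of member node identifiers, in input order.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Label of a seed set
#' @param x A SeedSet.
#' @return Single character label.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' Per-node scores
#' @param x A SimilarityScores or RankingTable.
#' @return Named numeric vector of scores.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Cluster labels
#' @param x A ClusterLabels object.
#' @return Named integer vector; -1 marks density-clustering noise.
#' @export
setGeneric("labels")

#' Permutation importance scores
#' @param x An ImportanceReport.
#' @return Named numeric vector, mean accuracy drop per measure.
#' @export
setGeneric("importance", function(x) standardGeneric("importance"))

#' @describeIn SeedSet-class seed members in input order
#' @param x object
#' @export
setMethod("members", "SeedSet", function(x) x@members)

#' @describeIn SeedSet-class label of the set
#' @export
setMethod("setName", "SeedSet", function(x) x@name)

#' @describeIn SeedSet-class number of seeds
#' @export
setMethod("length", "SeedSet", function(x) length(x@members))

#' @describeIn CentralityMatrix-class node identifiers (lexicographic)
#' @export
setMethod("nodeIds", "CentralityMatrix", function(x) rownames(x@values))

#' @describeIn CentralityMatrix-class measure labels in column order
#' @export
setMethod("measureNames", "CentralityMatrix", function(x) colnames(x@values))

#' @describeIn CentralityMatrix-class underlying numeric matrix
#' @export
setMethod("as.matrix", "CentralityMatrix", function(x, ...) x@values)

#' @describeIn CentralityMatrix-class dimensions (nodes, measures)
#' @export
setMethod("dim", "CentralityMatrix", function(x) dim(x@values))

#' @describeIn SimilarityScores-class named score vector
#' @param x object
#' @export
setMethod("scores", "SimilarityScores", function(x) x@scores)

#' @describeIn SimilarityScores-class node identifiers
#' @export
setMethod("nodeIds", "SimilarityScores", function(x) names(x@scores))

#' @describeIn RankingTable-class scores named by node, in rank order
#' @param x object
#' @export
setMethod("scores", "RankingTable", function(x)
  stats::setNames(x@table$score, x@table$node_id))

#' @describeIn RankingTable-class node identifiers in rank order
#' @export
setMethod("nodeIds", "RankingTable", function(x) x@table$node_id)

#' @describeIn RankingTable-class number of ranked nodes
#' @export
setMethod("length", "RankingTable", function(x) nrow(x@table))

#' @describeIn RankingTable-class underlying data.frame
#' @param row.names,optional,... passed through (unused)
#' @export
setMethod("as.data.frame", "RankingTable",
  function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' Ranker label of a RankingTable
#' @param x A RankingTable.
#' @return Single character method label.
#' @export
rankerMethod <- function(x) {
  stopifnot(is(x, "RankingTable"))
  x@method
}

#' @describeIn ClusterLabels-class named label vector (-1 = noise)
#' @param object object
#' @export
setMethod("labels", "ClusterLabels", function(object, ...) object@labels)

#' @describeIn ClusterLabels-class node identifiers
#' @param x object
#' @export
setMethod("nodeIds", "ClusterLabels", function(x) names(x@labels))

#' @describeIn ImportanceReport-class mean accuracy-drop per measure
#' @param x object
#' @export
setMethod("importance", "ImportanceReport", function(x) x@importance)

#' @describeIn ImportanceReport-class measure labels
#' @export
setMethod("measureNames", "ImportanceReport", function(x) names(x@importance))

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet '", object@name, "' with ", length(object@members),
      " members\n", sep = "")
  m <- object@members
  if (length(m) > 6) m <- c(m[1:6], "...")
  cat("  ", paste(m, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CentralityMatrix", function(object) {
  cat("CentralityMatrix: ", nrow(object@values), " nodes x ",
      ncol(object@values), " measures\n", sep = "")
  cat("  measures: ", paste(colnames(object@values), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "SimilarityScores", function(object) {
  cat("SimilarityScores for ", length(object@scores), " nodes, range [",
      sprintf("%.4f", min(object@scores)), ", ",
      sprintf("%.4f", max(object@scores)), "]\n", sep = "")
})

setMethod("show", "RankingTable", function(object) {
  cat("RankingTable (", object@method, "): ", nrow(object@table),
      " nodes\n", sep = "")
  print(utils::head(object@table, 5), row.names = FALSE)
  if (nrow(object@table) > 5) cat("  ...\n")
})

setMethod("show", "ClusterLabels", function(object) {
  tab <- table(object@labels)
  cat("ClusterLabels (", object@method, "): ", length(object@labels),
      " nodes in ", sum(names(tab) != "-1"), " cluster(s)",
      if ("-1" %in% names(tab)) paste0(" + ", tab[["-1"]], " noise"),
      "\n", sep = "")
})

setMethod("show", "ImportanceReport", function(object) {
  cat("ImportanceReport (labels: ", object@method, ", ", object@nTrees,
      " trees, ", object@nRepeats, " repeats, seed ", object@seed, ")\n",
      sep = "")
  ord <- order(-object@importance)
  df <- data.frame(measure = names(object@importance)[ord],
                   importance = object@importance[ord],
                   sd = object@importanceSd[ord])
  print(df, row.names = FALSE, digits = 4)
})
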