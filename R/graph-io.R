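## Reading and validating networks, seed lists, and rankings; writing
## tabular outputs. Networks are igraph objects; the loaders enforce the
## invariants every downstream step assumes: undirected, no self-loops,
## no parallel edges (collapsed, weights summed), strictly positive
## weights when present.

#' Lexicographic (byte-order) sort, locale-independent
#' @noRd
lexSort <- function(x) sort(x, method = "radix")

#' Construct a validated undirected network from an edge data.frame
#' @noRd
buildNetwork <- function(edges, weights = NULL, quiet = FALSE) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[[1]], to = edges[[2]],
               stringsAsFactors = FALSE),
    directed = FALSE)
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  nSelf <- sum(igraph::which_loop(g))
  nEdges0 <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "sum"))
  nDup <- nEdges0 - nSelf - igraph::ecount(g)
  if (!quiet && nSelf > 0)
    message(nSelf, " self-loop(s) removed")
  if (!quiet && nDup > 0)
    message(nDup, " duplicate edge(s) collapsed",
            if (!is.null(weights)) " (weights summed)")
  g
}

#' Load an undirected network from an edge-list file
#'
#' Reads a 2-column (or 3-column, when \code{weighted}) whitespace- or
#' tab-separated edge list. Lines starting with \code{#} are comments; in
#' weighted mode a single leading header line is auto-detected by a
#' non-numeric third field. Self-loops are dropped and parallel edges
#' collapsed (weights summed), with counts reported via \code{message()}.
#'
#' @param path Path to the edge-list file.
#' @param weighted Logical; expect a third, strictly positive weight column.
#' @param quiet Logical; suppress the cleanup messages.
#' @return An \code{igraph} undirected simple graph. Edge weights, if
#'   loaded, are in the \code{weight} edge attribute.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "a c"), f)
#' g <- loadEdgeList(f)
#' igraph::vcount(g)  # 3
loadEdgeList <- function(path, weighted = FALSE, quiet = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  fields <- strsplit(lines, "[ \t]+")
  want <- if (weighted) 3L else 2L
  nf <- lengths(fields)
  bad <- which(nf != want)
  # header auto-detection: first data line with a non-numeric weight field
  if (weighted && length(lines) > 1L && !length(bad) &&
      is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    fields <- fields[-1]
    lineNo <- lineNo[-1]
    nf <- nf[-1]
  } else if (length(bad)) {
    stop("malformed line ", lineNo[bad[1]], " in ", path, ": expected ",
         want, " fields, found ", nf[bad[1]])
  }
  from <- vapply(fields, `[`, "", 1L)
  to <- vapply(fields, `[`, "", 2L)
  w <- NULL
  if (weighted) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    if (anyNA(w))
      stop("malformed line ", lineNo[which(is.na(w))[1]], " in ", path,
           ": non-numeric weight")
    if (any(w <= 0))
      stop("non-positive weight on line ", lineNo[which(w <= 0)[1]],
           " in ", path)
  }
  buildNetwork(data.frame(from, to, stringsAsFactors = FALSE), w,
               quiet = quiet)
}

#' Load an undirected network from a GraphML file
#'
#' Alternate input format. The graph is coerced to the same invariants as
#' \code{\link{loadEdgeList}}: undirected, simple, positive weights.
#'
#' @inheritParams loadEdgeList
#' @return An \code{igraph} undirected simple graph.
#' @export
loadGraphML <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  hasW <- "weight" %in% igraph::edge_attr_names(g)
  g <- igraph::simplify(g, edge.attr.comb = if (hasW) list(weight = "sum") else
    igraph::igraph_opt("edge.attr.comb"))
  if (hasW && any(igraph::E(g)$weight <= 0))
    stop("non-positive edge weight in ", path)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Load a seed list and intersect it with a network
#'
#' Reads one node identifier per line (blank and \code{#} lines ignored,
#' duplicates dropped keeping first occurrence). Identifiers absent from
#' the network are reported, never silently dropped; if no seed is present
#' in the network the ranking is undefined and loading fails.
#'
#' @param path Path to the seed file.
#' @param network \code{igraph} network the seeds must live in.
#' @param name Label for the set; defaults to the file stem.
#' @param quiet Logical; suppress the missing-seed message.
#' @return A list with elements \code{seeds} (a \code{\linkS4class{SeedSet}})
#'   and \code{missing} (character vector of identifiers not in the network).
#' @export
loadSeeds <- function(path, network, name = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("seed file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0L) stop("seed file has no identifiers: ", path)
  ids <- ids[!duplicated(ids)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  present <- ids[ids %in% igraph::V(network)$name]
  missing <- setdiff(ids, present)
  if (length(present) == 0L)
    stop("none of the ", length(ids), " seeds in ", path,
         " are present in the network; ranking is undefined")
  if (!quiet && length(missing))
    message(length(missing), " seed(s) not in network: ",
            paste(missing, collapse = ", "))
  list(seeds = new("SeedSet", name = name, members = present),
       missing = missing)
}

#' Construct a SeedSet directly from identifiers
#'
#' @param members Character vector of unique node identifiers.
#' @param name Label for the set.
#' @return A \code{\linkS4class{SeedSet}}.
#' @export
seedSet <- function(members, name = "seeds") {
  new("SeedSet", name = name, members = as.character(members))
}

#' Write a tabular result as TSV
#'
#' All tabular outputs (rankings, centrality matrices, similarity tables,
#' overlap counts) go through this writer: tab-separated, header line,
#' floats at 6 significant digits, row order preserved.
#'
#' @param rows A data.frame, matrix, or any core result object coercible
#'   to a table (RankingTable, CentralityMatrix, SimilarityScores,
#'   ImportanceReport).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
writeResultTable <- function(rows, path) {
  df <- resultAsDataFrame(rows)
  if (nrow(df) == 0L) stop("refusing to write an empty table")
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Coerce a core result object to a plain data.frame
#' @noRd
resultAsDataFrame <- function(rows) {
  if (is(rows, "RankingTable")) return(rows@table)
  if (is(rows, "CentralityMatrix"))
    return(data.frame(node_id = rownames(rows@values), rows@values,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      row.names = NULL))
  if (is(rows, "SimilarityScores"))
    return(data.frame(node_id = names(rows@scores),
                      mean_similarity = unname(rows@scores),
                      stringsAsFactors = FALSE))
  if (is(rows, "ImportanceReport"))
    return(data.frame(measure = names(rows@importance),
                      importance = unname(rows@importance),
                      importance_sd = unname(rows@importanceSd),
                      method = rows@method, stringsAsFactors = FALSE))
  if (is.matrix(rows))
    return(data.frame(node_id = rownames(rows), rows, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL))
  as.data.frame(rows)
}

#' Read a ranking written by writeResultTable (or an external tool)
#'
#' Accepts the standard four-column ranking TSV (\code{node_id},
#' \code{score}, \code{rank}, \code{is_seed}); externally produced
#' rankings (e.g. embedding- or distance-based tools) can be fed to the
#' overlap analysis through this reader.
#'
#' @param path Path to the TSV file.
#' @param method Ranker label to attach; defaults to the file stem.
#' @return A \code{\linkS4class{RankingTable}}.
#' @export
readRankingTable <- function(path, method = NULL) {
  if (!file.exists(path)) stop("ranking file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(node_id = "character"))
  if (is.null(method)) method <- sub("\\.[^.]*$", "", basename(path))
  df <- df[order(df$rank), , drop = FALSE]
  row.names(df) <- NULL
  df$rank <- as.integer(df$rank)
  df$is_seed <- as.logical(df$is_seed)
  new("RankingTable", table = df[c("node_id", "score", "rank", "is_seed")],
      method = method)
}
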