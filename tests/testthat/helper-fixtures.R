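# Small construction helpers shared across test files.

# a CentralityMatrix from raw values (rows auto-sorted lexicographically)
cmFromMatrix <- function(vals) {
  if (is.null(colnames(vals)))
    colnames(vals) <- paste0("f", seq_len(ncol(vals)))
  vals <- vals[sort(rownames(vals), method = "radix"), , drop = FALSE]
  new("CentralityMatrix", values = vals)
}

# an igraph from a compact "a-b b-c" edge string
graphFromString <- function(s) {
  pairs <- strsplit(strsplit(trimws(s), "[ ]+")[[1]], "-")
  igraph::graph_from_data_frame(
    data.frame(from = vapply(pairs, `[`, "", 1),
               to = vapply(pairs, `[`, "", 2)),
    directed = FALSE)
}

# write lines to a temp file, return path
tmpLines <- function(...) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(c(...), f)
  f
}
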