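#' Read and write graphs as tab-separated edge lists
#'
#' The on-disk format is one undirected edge per row,
#' `u<TAB>v<TAB>weight`, with 0-based integer vertex ids. An edge listed in
#' both directions is accepted when the weights agree and rejected
#' otherwise; self-loop rows and negative weights are format errors.
#'
#' @param path file path.
#' @param G a [weighted_graph()].
#' @param N optional vertex count; defaults to 1 + the largest id seen, use
#'   it when trailing vertices are isolated.
#' @return `read_edgelist()` returns a [weighted_graph()];
#'   `write_edgelist()` returns `path` invisibly.
#' @export
read_edgelist <- function(path, N = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("u", "v", "w"),
                          colClasses = c("integer", "integer", "numeric"))
  if (nrow(df) == 0L) stop("empty edge list", call. = FALSE)
  if (any(df$u < 0L | df$v < 0L))
    stop("vertex ids must be 0-based nonnegative integers", call. = FALSE)
  if (any(df$u == df$v))
    stop("self-loop row in edge list (u == v)", call. = FALSE)
  if (any(!is.finite(df$w) | df$w < 0))
    stop("edge weights must be finite and nonnegative", call. = FALSE)
  n <- if (is.null(N)) max(df$u, df$v) + 1L else check_count(N, 2L, "N")
  w <- matrix(0, n, n)
  key <- paste(pmin(df$u, df$v), pmax(df$u, df$v))
  for (grp in split(seq_len(nrow(df)), key)) {
    vals <- df$w[grp]
    if (max(vals) - min(vals) > 0)
      stop("edge listed more than once with conflicting weights: ",
           df$u[grp[1]], "-", df$v[grp[1]], call. = FALSE)
    w[df$u[grp[1]] + 1L, df$v[grp[1]] + 1L] <- vals[1]
    w[df$v[grp[1]] + 1L, df$u[grp[1]] + 1L] <- vals[1]
  }
  weighted_graph(w)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(G, path) {
  G <- as_weighted_graph(G)
  idx <- which(upper.tri(G$w) & G$w > 0, arr.ind = TRUE)
  df <- data.frame(u = idx[, 1] - 1L, v = idx[, 2] - 1L,
                   w = G$w[idx])
  df <- df[order(df$u, df$v), ]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a graph as a JSON edge list
#'
#' @param G a [weighted_graph()].
#' @return JSON string `{"N": ..., "edges": [[u, v, w], ...]}` (0-based ids).
#' @export
graph_to_json <- function(G) {
  G <- as_weighted_graph(G)
  idx <- which(upper.tri(G$w) & G$w > 0, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(idx)), function(k)
    c(idx[k, 1] - 1L, idx[k, 2] - 1L, G$w[idx[k, 1], idx[k, 2]]))
  jsonlite::toJSON(list(N = G$N, edges = edges), auto_unbox = TRUE, digits = NA)
}
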