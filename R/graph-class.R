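#' Weighted undirected graph
#'
#' The basic population structure: `N` haploid individuals on the vertices of
#' a weighted, undirected graph with no self-loops. Edge weight `w[i, j]`
#' measures the strength of the spatial relationship between vertices `i` and
#' `j`; a zero weight means no edge.
#'
#' @param w square numeric matrix of nonnegative edge weights; must be
#'   symmetric with a zero diagonal.
#' @return An object of class `weighted_graph`: a list with elements `N`
#'   (vertex count) and `w` (the weight matrix).
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' weighted_degrees(g)
#' @export
weighted_graph <- function(w) {
  w <- as.matrix(w)
  if (!is.numeric(w) || nrow(w) != ncol(w))
    stop("`w` must be a square numeric matrix", call. = FALSE)
  N <- nrow(w)
  if (N < 2L) stop("a population needs at least 2 vertices", call. = FALSE)
  if (N > 2000L)
    stop("graphs above N = 2000 are not supported (dense weight storage)",
         call. = FALSE)
  if (anyNA(w) || any(w < 0))
    stop("edge weights must be nonnegative and finite", call. = FALSE)
  if (max(abs(w - t(w))) > 0)
    stop("weight matrix must be symmetric (undirected graph)", call. = FALSE)
  if (any(diag(w) != 0))
    stop("self-loops are not allowed (diagonal must be zero)", call. = FALSE)
  dimnames(w) <- NULL
  structure(list(N = N, w = w), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  ne <- sum(x$w[upper.tri(x$w)] > 0)
  cat("<weighted_graph> N =", x$N, "vertices,", ne, "edges\n")
  wd <- weighted_degrees(x)
  cat("  weighted degrees: min", format(min(wd)), " max", format(max(wd)), "\n")
  invisible(x)
}

as_weighted_graph <- function(g) {
  if (inherits(g, "weighted_graph")) return(g)
  weighted_graph(g)
}

#' Connectivity of the positive-weight graph
#'
#' @param G a [weighted_graph()].
#' @return `TRUE` if the graph restricted to strictly positive weights is
#'   connected.
#' @export
is_connected_graph <- function(G) {
  G <- as_weighted_graph(G)
  adj <- G$w > 0
  seen <- logical(G$N)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

stop_if_disconnected <- function(G) {
  if (!is_connected_graph(G))
    stop("graph is not connected; coalescence and fixation are undefined",
         call. = FALSE)
  invisible(G)
}

#' Weighted degrees, step probabilities and the stationary distribution
#'
#' The ancestral random walk steps from `i` to `j` with probability
#' `p[i, j] = w[i, j] / w_i`, where `w_i` is the weighted degree of `i`.
#' Its stationary distribution puts mass `pi_i = w_i / sum_j w_j` on vertex
#' `i`, i.e. mass proportional to relative weighted degree.
#'
#' @param G a [weighted_graph()].
#' @return `weighted_degrees()`: numeric vector of weighted degrees.
#' @export
weighted_degrees <- function(G) {
  G <- as_weighted_graph(G)
  rowSums(G$w)
}

#' @rdname weighted_degrees
#' @return `step_probabilities()`: row-stochastic N x N matrix of walk steps.
#' @export
step_probabilities <- function(G) {
  G <- as_weighted_graph(G)
  wd <- weighted_degrees(G)
  if (any(wd == 0))
    stop("isolated vertex (weighted degree 0): step probabilities undefined",
         call. = FALSE)
  G$w / wd
}

#' @rdname weighted_degrees
#' @return `stationary_distribution()`: probability vector summing to 1.
#' @export
stationary_distribution <- function(G) {
  G <- as_weighted_graph(G)
  stop_if_disconnected(G)
  wd <- weighted_degrees(G)
  wd / sum(wd)
}

#' Is the graph isothermal?
#'
#' A graph is isothermal when every vertex has the same weighted degree
#' (equivalently, the stationary distribution of the ancestral walk is
#' uniform). Isothermal graphs neither amplify nor suppress weak selection
#' under dB updating.
#'
#' @param G a [weighted_graph()].
#' @param tol relative tolerance on the spread of weighted degrees.
#' @return logical flag.
#' @export
is_isothermal <- function(G, tol = coalfix_tolerances()$isothermal) {
  G <- as_weighted_graph(G)
  wd <- weighted_degrees(G)
  wbar <- mean(wd)
  max(abs(wd - wbar)) <= tol * wbar
}

#' First two moments of the weighted degree distribution
#'
#' @param G a [weighted_graph()].
#' @return A list of class `degree_moments` with `mu1` (mean weighted degree)
#'   and `mu2` (mean squared weighted degree).
#' @export
degree_moments <- function(G) {
  G <- as_weighted_graph(G)
  wd <- weighted_degrees(G)
  structure(list(mu1 = mean(wd), mu2 = mean(wd^2)), class = "degree_moments")
}
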