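#' Graph family constructors
#'
#' Deterministic constructors for the graph families studied in the package.
#' All vertices are 0-based in file I/O but 1-based inside R matrices; hub
#' vertices always occupy the lowest indices so that closed-form cross-checks
#' are stable.
#'
#' @name graph-families
#' @param N population size.
#' @param n for the star: number of leaves; for Fan / Separated Hubs / Star
#'   of Islands: number of blades or islands (n >= 2).
#' @param m vertices per blade / island (m >= 2).
#' @param h number of hub vertices (Separated Hubs: h >= 1; Star of
#'   Islands: h >= 2).
#' @param eps weight of hub-to-blade (or hub-to-island) edges; must be
#'   strictly positive. The eps -> 0 limit disconnects the graph and is
#'   served by the closed-form functions, not by these constructors.
#' @return A [weighted_graph()].
NULL

#' @describeIn graph-families complete graph \eqn{K_N}: the well-mixed
#'   baseline, every pair joined with weight 1.
#' @export
make_complete <- function(N) {
  N <- check_count(N, 2L, "N")
  w <- matrix(1, N, N)
  diag(w) <- 0
  weighted_graph(w)
}

#' @describeIn graph-families star \eqn{S_n}: one hub (vertex 1) joined to
#'   each of `n` leaves with weight 1. A suppressor of selection under dB.
#' @export
make_star <- function(n) {
  n <- check_count(n, 2L, "n")
  w <- matrix(0, n + 1L, n + 1L)
  w[1L, -1L] <- 1
  w[-1L, 1L] <- 1
  weighted_graph(w)
}

#' @describeIn graph-families cycle \eqn{C_N}: the 2-regular ring, the
#'   canonical reducer of fixation under dB.
#' @export
make_cycle <- function(N) {
  N <- check_count(N, 3L, "N")
  w <- matrix(0, N, N)
  idx <- cbind(seq_len(N), c(seq_len(N)[-1L], 1L))
  w[idx] <- 1
  w[idx[, 2:1]] <- 1
  weighted_graph(w)
}

#' @describeIn graph-families Fan \eqn{F_{n,m}}: one hub plus `n` blades of
#'   `m` vertices; within-blade weights 1, hub-to-blade weights `eps`.
#'   Isothermal exactly when `eps = (m - 1) / (n * m - 1)`.
#' @export
make_fan <- function(n, m, eps) {
  make_separated_hubs(n, m, h = 1L, eps = eps)
}

#' @describeIn graph-families Separated Hubs \eqn{SH_{n,m,h}}: `h` mutually
#'   unconnected hubs, each joined to every blade vertex with weight `eps`;
#'   `n` blades of `m` vertices with within-blade weights 1. The Fan is the
#'   h = 1 case.
#' @export
make_separated_hubs <- function(n, m, h, eps) {
  n <- check_count(n, 2L, "n")
  m <- check_count(m, 2L, "m")
  h <- check_count(h, 1L, "h")
  check_eps(eps)
  N <- n * m + h
  w <- matrix(0, N, N)
  hub <- seq_len(h)
  for (b in seq_len(n)) {
    blade <- h + (b - 1L) * m + seq_len(m)
    w[blade, blade] <- 1
  }
  w[hub, -hub] <- eps
  w[-hub, hub] <- eps
  diag(w) <- 0
  weighted_graph(w)
}

#' @describeIn graph-families Star of Islands \eqn{SI_{n,m,h}}: a hub island
#'   of `h` vertices (pairwise weight 1) and `n` islands of `m` vertices
#'   (pairwise weight 1 within an island); every hub-island pair joined with
#'   weight `eps`.
#' @export
make_star_of_islands <- function(n, m, h, eps) {
  n <- check_count(n, 2L, "n")
  m <- check_count(m, 2L, "m")
  h <- check_count(h, 2L, "h")
  check_eps(eps)
  N <- n * m + h
  w <- matrix(0, N, N)
  hub <- seq_len(h)
  w[hub, hub] <- 1
  for (b in seq_len(n)) {
    island <- h + (b - 1L) * m + seq_len(m)
    w[island, island] <- 1
  }
  w[hub, -hub] <- eps
  w[-hub, hub] <- eps
  diag(w) <- 0
  weighted_graph(w)
}

#' Random graph generators
#'
#' Seeded generators for the random-graph ensembles used to survey how common
#' amplifiers and suppressors of weak selection are. All edges have weight 1.
#'
#' @name random-graphs
#' @param N population size.
#' @param seed integer RNG seed; the same seed reproduces the same graph.
#' @return A [weighted_graph()]. The number of rejected (disconnected or
#'   otherwise infeasible) draws is attached as attribute `"redraws"`.
NULL

igraph_to_wg <- function(g) {
  weighted_graph(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

#' @describeIn random-graphs Erdős–Rényi \eqn{G(N, p)} with
#'   `p = mean_degree / (N - 1)`. By default disconnected draws are rejected
#'   and redrawn, since the effective population size is undefined on
#'   disconnected graphs; set `require_connected = FALSE` to keep the first
#'   draw regardless.
#' @param mean_degree target expected degree \eqn{\langle k \rangle}.
#' @param require_connected reject and redraw disconnected graphs?
#' @param max_attempts redraw budget before giving up.
#' @export
make_erdos_renyi <- function(N, mean_degree, seed,
                             require_connected = TRUE,
                             max_attempts = 10000L) {
  N <- check_count(N, 2L, "N")
  p <- mean_degree / (N - 1)
  if (!is.finite(p) || p <= 0 || p > 1)
    stop("mean_degree must give a link probability in (0, 1]; need N >= mean_degree + 1",
         call. = FALSE)
  set.seed(seed)
  redraws <- 0L
  repeat {
    g <- igraph_to_wg(igraph::sample_gnp(N, p))
    if (!require_connected || is_connected_graph(g)) break
    redraws <- redraws + 1L
    if (redraws >= max_attempts)
      stop("no connected Erdos-Renyi draw within ", max_attempts, " attempts",
           call. = FALSE)
  }
  attr(g, "redraws") <- redraws
  g
}

#' @describeIn random-graphs Barabási–Albert preferential attachment:
#'   growth from a complete seed graph of `m_links + 2` vertices, each new
#'   vertex attaching `m_links` edges. Always connected.
#' @param m_links number of edges each arriving vertex attaches.
#' @export
make_barabasi_albert <- function(N, m_links, seed) {
  N <- check_count(N, 2L, "N")
  m_links <- check_count(m_links, 1L, "m_links")
  if (N < m_links + 2L)
    stop("need N >= m_links + 2 (the complete seed graph)", call. = FALSE)
  set.seed(seed)
  start <- igraph::make_full_graph(m_links + 2L)
  g <- igraph::sample_pa(N, m = m_links, directed = FALSE, start.graph = start)
  g <- igraph_to_wg(igraph::simplify(g))
  attr(g, "redraws") <- 0L
  g
}

#' @describeIn random-graphs random `k`-regular graph (configuration /
#'   pairing model, simple graphs only); disconnected draws are rejected.
#' @param k common degree; `N * k` must be even and `k < N`.
#' @export
make_random_regular <- function(N, k, seed, max_attempts = 10000L) {
  N <- check_count(N, 2L, "N")
  k <- check_count(k, 1L, "k")
  if ((N * k) %% 2L != 0L || k >= N)
    stop("infeasible degree sequence: need N*k even and k < N", call. = FALSE)
  set.seed(seed)
  redraws <- 0L
  repeat {
    g <- igraph_to_wg(igraph::sample_k_regular(N, k))
    if (is_connected_graph(g)) break
    redraws <- redraws + 1L
    if (redraws >= max_attempts)
      stop("no connected ", k, "-regular draw within ", max_attempts,
           " attempts", call. = FALSE)
  }
  attr(g, "redraws") <- redraws
  g
}

check_count <- function(x, lo, name) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < lo)
    stop("`", name, "` must be a single integer >= ", lo, call. = FALSE)
  as.integer(x)
}

check_eps <- function(eps) {
  if (length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("`eps` must be a single strictly positive number; the eps -> 0 ",
         "limit is available through the closed-form functions", call. = FALSE)
  invisible(eps)
}
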