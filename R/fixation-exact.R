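#' Exact fixation probability from the full absorbing Markov chain
#'
#' Enumerates all `2^N` mutant configurations as bitmasks and solves the
#' absorption system of the death-Birth process directly (sparse LU). One
#' step: a death vertex `d` is drawn uniformly; the vacancy is filled by
#' neighbor `j` with probability proportional to `f_j * w[j, d]`, where
#' `f_j = r` for mutants and 1 for residents. The returned value is the
#' uniform average over single-mutant starting vertices of the probability
#' of reaching the all-mutant state.
#'
#' @param G a connected [weighted_graph()].
#' @param r mutant fitness, \eqn{r > 0}.
#' @param cap refuse graphs above this size (the chain has `2^N` states).
#' @param per_vertex also return the fixation probability from each
#'   single-mutant start.
#' @return The fixation probability (scalar), or, with `per_vertex = TRUE`,
#'   a list with `rho` and the per-start vector `rho_vertex`.
#' @examples
#' rho_exact(make_complete(3), r = 2)   # 4/9
#' @export
rho_exact <- function(G, r, cap = 14L, per_vertex = FALSE) {
  G <- as_weighted_graph(G)
  stop_if_disconnected(G)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive fitness value", call. = FALSE)
  N <- G$N
  if (N > cap)
    stop("N = ", N, " exceeds the 2^N chain cap (", cap, ")", call. = FALSE)
  w <- G$w
  wd <- rowSums(w)
  nstate <- 2L^N
  states <- 0:(nstate - 1L)
  bit <- 2L^(0:(N - 1L))

  # membership[s, d] = is vertex d mutant in state s
  member <- outer(states, bit, function(s, b) bitwAnd(s, b) > 0L)
  a <- member %*% w                       # mutant weight into each vertex
  b <- matrix(wd, nstate, N, byrow = TRUE) - a
  denom <- r * a + b                      # = wd + (r-1) a, always > 0
  p_up <- (r * a / denom) / N             # d resident -> becomes mutant
  p_down <- (b / denom) / N               # d mutant  -> becomes resident

  transient <- states[states != 0L & states != nstate - 1L]
  tmap <- integer(nstate)
  tmap[transient + 1L] <- seq_along(transient)

  src <- integer(0); dst <- integer(0); val <- numeric(0)
  for (d in seq_len(N)) {
    up <- which(!member[, d])             # states where d is resident
    s_up <- states[up]
    keep <- s_up != 0L & s_up != nstate - 1L
    src <- c(src, s_up[keep]); dst <- c(dst, s_up[keep] + bit[d])
    val <- c(val, p_up[up, d][keep])
    down <- which(member[, d])
    s_dn <- states[down]
    keep <- s_dn != 0L & s_dn != nstate - 1L
    src <- c(src, s_dn[keep]); dst <- c(dst, s_dn[keep] - bit[d])
    val <- c(val, p_down[down, d][keep])
  }
  nt <- length(transient)
  agg <- rowsum(val, src)                 # total move probability per state
  move_tot <- numeric(nstate)
  move_tot[as.integer(rownames(agg)) + 1L] <- agg
  to_full <- dst == nstate - 1L
  b_full <- numeric(nstate)
  if (any(to_full)) {
    aggf <- rowsum(val[to_full], src[to_full])
    b_full[as.integer(rownames(aggf)) + 1L] <- aggf
  }
  inner <- !to_full & dst != 0L
  L <- Matrix::sparseMatrix(i = tmap[src[inner] + 1L], j = tmap[dst[inner] + 1L],
                            x = -val[inner], dims = c(nt, nt)) +
    Matrix::Diagonal(x = move_tot[transient + 1L])
  # hypercube adjacency causes heavy sparse-LU fill-in; dense LU via BLAS is
  # faster until the state space outgrows memory
  bvec <- b_full[transient + 1L]
  x <- if (nt <= 10000) solve(as.matrix(L), bvec)
       else as.numeric(Matrix::solve(L, bvec))

  rho_vertex <- x[tmap[bit + 1L]]
  rho <- mean(rho_vertex)
  if (per_vertex) list(rho = rho, rho_vertex = rho_vertex) else rho
}
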