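#' Pairwise coalescence times of the ancestral random walk
#'
#' Two walkers trace the ancestry of a pair of individuals backwards in time;
#' at each step one of the two (chosen with equal probability) moves according
#' to the step probabilities `p[i, j] = w[i, j] / w_i`. The expected meeting
#' time `tau[i, j]` from starting vertices `i`, `j` satisfies the linear
#' system
#' \deqn{\tau_{ii} = 0, \qquad
#'   \tau_{ij} = 1 + \tfrac12 \sum_k (p_{ik}\tau_{jk} + p_{jk}\tau_{ik}),
#'   \quad i \ne j,}
#' which is solved here as one sparse linear system in the N(N-1)/2
#' unordered-pair unknowns.
#'
#' @param G a connected [weighted_graph()].
#' @return Symmetric N x N matrix of coalescence times (zero diagonal). The
#'   maximum equation residual is attached as attribute `"residual"`.
#' @export
coalescence_times <- function(G) {
  G <- as_weighted_graph(G)
  stop_if_disconnected(G)
  N <- G$N
  p <- step_probabilities(G)

  # unordered-pair index: pid[i, j] = position of {i, j}, i < j
  pid <- matrix(0L, N, N)
  ut <- which(upper.tri(pid))
  pid[ut] <- seq_along(ut)
  pid <- pid + t(pid)
  np <- length(ut)

  # row pair {a, j}, walker at a steps to k: coefficient p[a, k] / 2 on
  # unknown tau[j, k]; expanding every directed edge (a, k) over all j
  # covers both sums of the update (a plays the role of i and of j in turn).
  ek <- which(p > 0, arr.ind = TRUE)
  ne <- nrow(ek)
  a <- rep(ek[, 1], each = N)
  k <- rep(ek[, 2], each = N)
  v <- rep(p[ek] / 2, each = N)
  j <- rep.int(seq_len(N), ne)
  keep <- (j != a) & (j != k)   # {a, j} must be a pair; tau[j, j] = 0 drops out
  rows <- pid[cbind(a[keep], j[keep])]
  cols <- pid[cbind(j[keep], k[keep])]

  A <- Matrix::Diagonal(np) -
    Matrix::sparseMatrix(i = rows, j = cols, x = v[keep], dims = c(np, np))
  # the pair system is small but fairly dense per row; dense LU (BLAS) beats
  # sparse LU fill-in until the matrix no longer fits comfortably in memory
  solve_sys <- if (np <= 6000) {
    Ad <- as.matrix(A)
    function(b) solve(Ad, b)
  } else function(b) as.numeric(Matrix::solve(A, b))
  ones <- rep(1, np)
  tau_u <- solve_sys(ones)

  # iterative refinement: near-degenerate graphs (e.g. hub weights ~1e-6)
  # are ill-conditioned enough to leave a visible residual after one LU pass
  tol <- coalfix_tolerances()$residual
  for (pass in 1:3) {
    resid <- ones - as.numeric(A %*% tau_u)
    if (max(abs(resid)) <= tol / 10) break
    tau_u <- tau_u + solve_sys(resid)
  }

  tau <- matrix(0, N, N)
  tau[ut] <- tau_u
  tau <- tau + t(tau)

  # residual check on the original (unreduced) equations
  rhs <- 1 + (p %*% tau + t(p %*% tau)) / 2
  res <- max(abs(tau - rhs)[upper.tri(tau)])
  if (res > tol)
    stop("coalescence system residual ", format(res),
         " exceeds tolerance ", format(tol), call. = FALSE)
  attr(tau, "residual") <- res
  tau
}

#' Remeeting times
#'
#' Expected time for two independent walkers launched from the same vertex to
#' meet again: `tau_i = 1 + sum_j p[i, j] * tau[i, j]`.
#'
#' @param G a connected [weighted_graph()].
#' @param tau_pair matrix from [coalescence_times()]; recomputed if missing.
#' @return Numeric vector of remeeting times.
#' @export
remeeting_times <- function(G, tau_pair = NULL) {
  G <- as_weighted_graph(G)
  if (is.null(tau_pair)) tau_pair <- coalescence_times(G)
  if (!is.matrix(tau_pair) || any(dim(tau_pair) != G$N))
    stop("`tau_pair` must be an N x N matrix matching the graph", call. = FALSE)
  p <- step_probabilities(G)
  1 + rowSums(p * tau_pair)
}

#' Effective population size from coalescing random walks
#'
#' Solves the coalescence system, forms the remeeting times and the
#' stationary distribution, and returns the effective population size
#' \eqn{N_{eff} = \sum_i \pi_i \tau_i}. A graph with `N_eff > N` is an
#' amplifier of weak selection; `N_eff < N`, a suppressor. The Kac
#' return-time identity \eqn{\sum_i \pi_i^2 \tau_i = 1} is checked as an
#' internal consistency diagnostic.
#'
#' @param G a connected [weighted_graph()].
#' @return An object of class `coalescence_result`: list with `tau_pair`,
#'   `tau_remeet`, `pi`, `n_eff`, and `kac_residual`.
#' @examples
#' res <- effective_population_size(make_star(5))
#' res$n_eff            # 4n/(n+1) = 10/3 for the 5-leaf star
#' @export
effective_population_size <- function(G) {
  G <- as_weighted_graph(G)
  tau <- coalescence_times(G)
  tau_i <- remeeting_times(G, tau)
  pi_i <- stationary_distribution(G)
  kac <- abs(sum(pi_i^2 * tau_i) - 1)
  if (kac > coalfix_tolerances()$kac)
    warning("Kac identity residual ", format(kac),
            " above tolerance; solution may be inaccurate")
  structure(list(tau_pair = tau, tau_remeet = tau_i, pi = pi_i,
                 n_eff = sum(pi_i * tau_i), N = G$N,
                 kac_residual = kac),
            class = "coalescence_result")
}

#' @export
print.coalescence_result <- function(x, ...) {
  cat("<coalescence_result> N =", x$N,
      " N_eff =", format(x$n_eff, digits = 8),
      " ratio =", format(x$n_eff / x$N, digits = 6), "\n")
  cat("  Kac residual:", format(x$kac_residual), "\n")
  invisible(x)
}

#' Weak-selection expansion of fixation probability
#'
#' For mutant fitness \eqn{r = 1 + \delta} with small `delta`, the fixation
#' probability on any connected graph expands as
#' \deqn{\rho_G(1+\delta) = 1/N + \delta (N_{eff} - 2) / (2N) + O(\delta^2).}
#'
#' @param G a connected [weighted_graph()].
#' @return An object of class `weak_selection_result`: list with `n_eff`, `N`,
#'   `slope` (the first-order coefficient), and `rho_at(delta)`, the affine
#'   map `delta -> 1/N + delta * slope`.
#' @export
weak_selection_fixation <- function(G) {
  res <- effective_population_size(G)
  slope <- (res$n_eff - 2) / (2 * res$N)
  N <- res$N
  structure(list(n_eff = res$n_eff, N = N, slope = slope,
                 rho_at = function(delta) 1 / N + delta * slope),
            class = "weak_selection_result")
}

#' @export
print.weak_selection_result <- function(x, ...) {
  cat("<weak_selection_result> rho(1+d) = 1/", x$N, " + d * ",
      format(x$slope, digits = 8), " + O(d^2)\n", sep = "")
  invisible(x)
}

#' Covariance identity linking N_eff to the stationary distribution
#'
#' The deficit `(N - N_eff) / N^2` equals the covariance, over vertices, of
#' `pi_i` with `pi_i * tau_i`; a graph amplifies weak selection exactly when
#' this covariance is negative. Returns the absolute residual of the
#' identity, which should vanish to numerical precision.
#'
#' @param G a connected [weighted_graph()].
#' @param result optional precomputed [effective_population_size()] output.
#' @return List with `residual` (nonnegative) and `covariance`.
#' @export
covariance_identity_residual <- function(G, result = NULL) {
  if (is.null(result)) result <- effective_population_size(G)
  N <- result$N
  pi_i <- result$pi
  tau_i <- result$tau_remeet
  cv <- mean(pi_i * pi_i * tau_i) - mean(pi_i) * mean(pi_i * tau_i)
  list(residual = abs((N - result$n_eff) / N^2 - cv), covariance = cv)
}

#' Mean-field approximation to the effective population size
#'
#' Assuming all remeeting times equal a common value, the Kac identity gives
#' \eqn{N_{eff} \approx N \mu_1^2 / \mu_2}, where \eqn{\mu_1, \mu_2} are the
#' first two moments of the weighted degree distribution. The approximation
#' is at most `N`, with equality only for isothermal graphs, so it can never
#' detect an amplifier of weak selection.
#'
#' @param G a [weighted_graph()].
#' @return Approximate effective population size (positive scalar).
#' @export
meanfield_neff <- function(G) {
  mom <- degree_moments(G)
  as_weighted_graph(G)$N * mom$mu1^2 / mom$mu2
}

#' Binomial mean-field prediction for Erdős–Rényi graphs
#'
#' Treating each degree as an independent Binom(N-1, p) draw in the
#' mean-field formula yields
#' \eqn{N_{eff}/N \approx (N-1)p / ((N-2)p + 1)}.
#'
#' @param N population size.
#' @param p link probability in (0, 1].
#' @return The predicted ratio `N_eff / N`.
#' @export
er_meanfield_ratio <- function(N, p) {
  N <- check_count(N, 2L, "N")
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("`p` must be a probability in (0, 1]", call. = FALSE)
  (N - 1) * p / ((N - 2) * p + 1)
}

#' Sensitivity of N_eff to an edge-weight perturbation of an isothermal graph
#'
#' At an isothermal graph the effective size equals N; perturbing edge
#' weights in a direction `d w[i, j] / d eps` changes it at first order by
#' \deqn{dN_{eff}/d\epsilon = - \sum_i \tau_i \, d\pi_i/d\epsilon,}
#' with the stationary-distribution derivative computed analytically from
#' the degree perturbation. Directions that lower the relative degree of
#' vertices with large remeeting time produce amplifiers of weak selection.
#'
#' @param G0 an isothermal, connected [weighted_graph()].
#' @param perturb 3-column matrix (or data frame) `(i, j, dw)` of 1-based
#'   vertex pairs and the derivative of their edge weight.
#' @return The derivative of `N_eff` with respect to the perturbation size.
#' @export
neff_gradient <- function(G0, perturb) {
  G0 <- as_weighted_graph(G0)
  if (!is_isothermal(G0))
    stop("`G0` must be isothermal (the gradient formula holds at N_eff = N)",
         call. = FALSE)
  perturb <- as.matrix(perturb)
  if (ncol(perturb) != 3L) stop("`perturb` needs columns (i, j, dw)", call. = FALSE)
  i <- as.integer(perturb[, 1]); j <- as.integer(perturb[, 2])
  if (any(i == j) || any(i < 1L) || any(j < 1L) || any(i > G0$N) || any(j > G0$N))
    stop("perturbed edges must join distinct vertices inside the graph",
         call. = FALSE)
  dwv <- perturb[, 3]
  ddeg <- numeric(G0$N)
  for (k in seq_along(i)) {
    ddeg[i[k]] <- ddeg[i[k]] + dwv[k]
    ddeg[j[k]] <- ddeg[j[k]] + dwv[k]
  }
  wd <- weighted_degrees(G0)
  W <- sum(wd)
  dpi <- (ddeg * W - wd * sum(ddeg)) / W^2
  tau_i <- remeeting_times(G0)
  -sum(tau_i * dpi)
}

#' Construct an amplifier of weak selection from an isothermal graph
#'
#' Implements the perturbation recipe: find the vertex with the largest
#' remeeting time (ties broken by smallest index), pick the incident edge
#' whose weight reduction has the largest positive `N_eff` gradient (or a
#' caller-specified neighbor), and reduce that edge weight by `eps`.
#'
#' @param G0 an isothermal, connected [weighted_graph()].
#' @param eps amount by which the chosen edge weight is reduced; must not
#'   exceed the edge weight.
#' @param neighbor optional 1-based index of the neighbor to use instead of
#'   the gradient-maximizing one.
#' @return List with the perturbed `graph`, its [effective_population_size()]
#'   `result`, the chosen `edge` (pair of vertex indices), the analytic
#'   `gradient` at eps = 0, and the logical `amplifier` (`n_eff > N`).
#' @export
construct_amplifier <- function(G0, eps, neighbor = NULL) {
  G0 <- as_weighted_graph(G0)
  if (!is_isothermal(G0)) stop("`G0` must be isothermal", call. = FALSE)
  if (eps < 0) stop("`eps` must be nonnegative", call. = FALSE)
  tau_i <- remeeting_times(G0)
  v <- which.max(tau_i)           # which.max already takes the smallest index
  nbrs <- which(G0$w[v, ] > 0)
  if (is.null(neighbor)) {
    grads <- vapply(nbrs, function(u)
      neff_gradient(G0, cbind(v, u, -1)), numeric(1))
    u <- nbrs[which.max(grads)]
    grad <- max(grads)
  } else {
    u <- as.integer(neighbor)
    if (!(u %in% nbrs)) stop("`neighbor` is not adjacent to the chosen vertex",
                             call. = FALSE)
    grad <- neff_gradient(G0, cbind(v, u, -1))
  }
  if (eps > G0$w[v, u])
    stop("`eps` exceeds the weight of the chosen edge", call. = FALSE)
  w <- G0$w
  w[v, u] <- w[v, u] - eps
  w[u, v] <- w[v, u]
  g <- weighted_graph(w)
  if (!is_connected_graph(g))
    stop("perturbation disconnects the graph", call. = FALSE)
  res <- effective_population_size(g)
  list(graph = g, result = res, edge = c(v, u), gradient = grad,
       amplifier = res$n_eff > G0$N)
}
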