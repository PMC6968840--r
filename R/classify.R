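#' Weak-selection classification
#'
#' A graph amplifies weak selection when its effective population size
#' exceeds the actual size, and suppresses it when `N_eff < N`; isothermal
#' graphs sit exactly on the boundary.
#'
#' @param G a connected [weighted_graph()].
#' @param tol relative tolerance on `(N_eff - N) / N` below which the graph
#'   is called neither.
#' @return One of `"amplifier-of-weak-selection"`,
#'   `"suppressor-of-weak-selection"`, `"neither"`.
#' @export
classify_weak <- function(G, tol = 1e-8) {
  res <- effective_population_size(G)
  d <- res$n_eff - res$N
  if (d > tol * res$N) "amplifier-of-weak-selection"
  else if (d < -tol * res$N) "suppressor-of-weak-selection"
  else "neither"
}

#' Full-range classification against the well-mixed baseline
#'
#' Compares a fixation-probability curve `rho_fn(r)` against the complete
#' graph of the same size, pointwise over a fitness grid straddling \eqn{r = 1}:
#' \itemize{
#'   \item amplifier: below the baseline for \eqn{r < 1}, above for \eqn{r > 1};
#'   \item suppressor: above for \eqn{r < 1}, below for \eqn{r > 1};
#'   \item transient amplifier: below for \eqn{r < 1}, above on \eqn{1 < r < r^*},
#'     below again for \eqn{r > r^*} (exactly one sign change above 1; \eqn{r^*} is
#'     refined by bisection);
#'   \item reducer: below the baseline for every \eqn{r \ne 1}.
#' }
#' Because every curve is tangent to the baseline at \eqn{r = 1}, grid points
#' where the two curves agree to within the relative tolerance are treated
#' as ties and excluded from the sign pattern. Verdicts are grid-bounded:
#' behavior beyond the grid maximum is not probed.
#'
#' @param rho_fn vectorized function of `r` returning fixation
#'   probabilities.
#' @param N population size of the baseline complete graph; `Inf` uses the
#'   large-population limit `max(0, 1 - 1/r)`.
#' @param r_grid fitness grid (default 200 log-spaced points on
#'   `[0.05, 50]`).
#' @param tol relative tie tolerance.
#' @return An object of class `classification_report`: list with `verdict`
#'   (`"amplifier"`, `"suppressor"`, `"transient-amplifier"`, `"reducer"`,
#'   `"neutral-equivalent"` or `"indeterminate"`), `r_star` (crossing point,
#'   only for transient amplifiers), `sign_pattern`, `r_grid`, `tolerance`.
#' @examples
#' classify_full(function(r) rho_cycle(6, r), N = 6)$verdict   # "reducer"
#' @export
classify_full <- function(rho_fn, N,
                          r_grid = exp(seq(log(0.05), log(50), length.out = 200)),
                          tol = coalfix_tolerances()$classify_rel) {
  baseline <- baseline_rho(N)
  rho_g <- rho_fn(r_grid)
  if (any(!is.finite(rho_g)) || any(rho_g < -tol) || any(rho_g > 1 + tol))
    stop("`rho_fn` returned values outside [0, 1]", call. = FALSE)
  rho_k <- baseline(r_grid)
  diff <- rho_g - rho_k
  tie <- abs(diff) <= tol * pmax(rho_k, 1 / max(N, 2))
  sgn <- sign(diff)
  sgn[tie] <- 0L

  lo <- sgn[r_grid < 1 & sgn != 0]
  hi_idx <- which(r_grid > 1 & sgn != 0)
  hi <- sgn[hi_idx]

  verdict <- "indeterminate"
  r_star <- NULL
  if (length(lo) == 0 && length(hi) == 0) {
    verdict <- "neutral-equivalent"
  } else if (all(lo < 0) && length(hi) && all(hi > 0)) {
    verdict <- "amplifier"
  } else if (all(lo > 0) && length(hi) && all(hi < 0)) {
    verdict <- "suppressor"
  } else if (all(lo < 0) && length(hi) && all(hi < 0)) {
    verdict <- "reducer"
  } else if (all(lo < 0) && length(hi) &&
             sum(diff(hi) != 0) == 1 && hi[1] > 0 && hi[length(hi)] < 0) {
    verdict <- "transient-amplifier"
    flip <- max(which(hi > 0))
    r_star <- find_crossing(rho_fn, N,
                            bracket = r_grid[hi_idx[c(flip, flip + 1L)]])
  }
  structure(list(verdict = verdict, r_star = r_star,
                 sign_pattern = rle(sgn[sgn != 0])$values,
                 r_grid = r_grid, tolerance = tol),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>", x$verdict)
  if (!is.null(x$r_star)) cat("  r* =", format(x$r_star, digits = 8))
  cat("\n  sign pattern of rho_G - rho_K over the grid:",
      paste(c("-" , "0", "+")[x$sign_pattern + 2], collapse = " "), "\n")
  invisible(x)
}

baseline_rho <- function(N) {
  if (is.infinite(N)) function(r) pmax(0, 1 - 1 / r)
  else function(r) rho_complete(N, r)
}

#' Locate the crossing point r* with the well-mixed curve
#'
#' Bisection root of `rho_fn(r) - rho_baseline(r)` inside a bracket where
#' the difference changes sign exactly once. For a transient amplifier this
#' is the fitness above which amplification turns into suppression.
#'
#' @inheritParams classify_full
#' @param bracket interval `(lo, hi)` bracketing the sign change (both
#'   endpoints above 1 in typical use).
#' @return The crossing fitness \eqn{r^*}.
#' @export
find_crossing <- function(rho_fn, N, bracket) {
  baseline <- baseline_rho(N)
  f <- function(r) rho_fn(r) - baseline(r)
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("no sign change of rho_G - rho_K inside the bracket", call. = FALSE)
  stats::uniroot(f, bracket, tol = coalfix_tolerances()$root)$root
}
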