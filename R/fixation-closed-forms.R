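#' Closed-form fixation probabilities for named graph families
#'
#' Analytic fixation probabilities under death-Birth updating, with a single
#' mutant placed uniformly at random. The complete graph, star and cycle
#' forms are exact at any edge weight; the Fan, Separated Hubs and Star of
#' Islands forms are the `eps -> 0` limits of vanishing hub-edge weight.
#' Every form with a removable singularity at \eqn{r = 1} switches to its
#' first-order expansion `1/N + (r-1)(N_eff - 2)/(2N)` inside a narrow
#' window around 1 (default half-width 1e-6), which keeps the curves
#' continuous across the seam to ~1e-9.
#'
#' @name rho-closed-forms
#' @inheritParams graph-families
#' @param r mutant fitness (positive scalar or vector).
#' @return Fixation probability in `[0, 1]`, vectorized over `r`.
NULL

series_window <- function() coalfix_tolerances()$series_window

check_r <- function(r) {
  if (length(r) < 1L || any(!is.finite(r)) || any(r <= 0))
    stop("`r` must be positive and finite", call. = FALSE)
  invisible(r)
}

# evaluate `formula(r)` away from r = 1 and the linear weak-selection
# expansion with the given N, N_eff inside the window
with_series_fallback <- function(r, N, n_eff, formula) {
  check_r(r)
  out <- numeric(length(r))
  near <- abs(r - 1) < series_window()
  if (any(near)) out[near] <- 1 / N + (r[near] - 1) * (n_eff - 2) / (2 * N)
  if (any(!near)) out[!near] <- formula(r[!near])
  out
}

#' @describeIn rho-closed-forms complete graph \eqn{K_N} (well-mixed
#'   baseline): \eqn{\rho = \frac{N-1}{N}\,\frac{1 - r^{-1}}{1 - r^{-(N-1)}}}.
#' @export
rho_complete <- function(N, r) {
  N <- check_count(N, 2L, "N")
  with_series_fallback(r, N, N, function(r)
    (N - 1) / N * (1 - r^-1) / (1 - r^-(N - 1)))
}

#' @describeIn rho-closed-forms star \eqn{S_n} with `n` leaves
#'   (`N = n + 1`); a suppressor of selection for dB updating.
#' @export
rho_star <- function(n, r) {
  n <- check_count(n, 2L, "n")
  check_r(r)
  N <- n + 1
  ((N - 1) * r + 1) / (N * (r + 1)) * (1 / N + r / (N + 2 * r - 2))
}

#' @describeIn rho-closed-forms cycle \eqn{C_N}; a reducer of fixation:
#'   below the well-mixed curve for every \eqn{r != 1}.
#' @export
rho_cycle <- function(N, r) {
  N <- check_count(N, 3L, "N")
  with_series_fallback(r, N, N, function(r)
    2 * (r - 1) / (3 * r - 1 + r^-(N - 3) - 3 * r^-(N - 2)))
}

#' @describeIn rho-closed-forms Fan \eqn{F_{n,m}} in the eps -> 0 limit
#'   (`N = nm + 1`, limit `N_eff = nm + n - 1`).
#' @export
rho_fan_limit <- function(n, m, r) {
  rho_sh_limit(n, m, h = 1L, r = r)
}

#' @describeIn rho-closed-forms Separated Hubs \eqn{SH_{n,m,h}} in the
#'   eps -> 0 limit (`N = nm + h`); reduces to the Fan at `h = 1`.
#' @export
rho_sh_limit <- function(n, m, h, r) {
  n <- as.numeric(check_count(n, 2L, "n"))
  m <- as.numeric(check_count(m, 2L, "m"))
  h <- as.numeric(check_count(h, 1L, "h"))
  N <- n * m + h
  with_series_fallback(r, N, n * m + n - 1, function(r)
    n * (m - 1) * (1 - r^-1) * (1 - r^-(m + 1)) /
      ((m * n + h) * (1 - r^-(m - 1)) * (1 - r^-(n * (m + 1)))))
}

#' @describeIn rho-closed-forms Separated Hubs in the additional limit of
#'   many blades (n -> infinity): 0 for \eqn{r <= 1}, positive above.
#' @export
rho_sh_inf <- function(m, r) {
  m <- check_count(m, 2L, "m")
  check_r(r)
  out <- numeric(length(r))
  hi <- r > 1
  out[hi] <- (m - 1) / m * (1 - r[hi]^-1) * (1 - r[hi]^-(m + 1)) /
    (1 - r[hi]^-(m - 1))
  out
}

#' @describeIn rho-closed-forms Star of Islands \eqn{SI_{n,m,h}} in the
#'   eps -> 0 limit (`N = nm + h`).
#' @export
rho_si_limit <- function(n, m, h, r) {
  n <- as.numeric(check_count(n, 2L, "n"))
  m <- as.numeric(check_count(m, 2L, "m"))
  h <- as.numeric(check_count(h, 2L, "h"))
  N <- n * m + h
  with_series_fallback(r, N, closed_form_neff_si_limit(n, m, h), function(r) {
    x <- (m * r^-m * (r^(m - 1) - 1) + h * (r^(h - 1) - 1)) /
      (m * r^h * (r^(m - 1) - 1) + h * (r^(h - 1) - 1))
    num <- r^m * (1 - r^-1) * (1 - r^-(h + m)) *
      (h * r^h * (1 - r^-(h - 1)) * (m * n * (m - 1) * r^m + h * (h - 1)) +
         m * r^m * (1 - r^-(m - 1)) * (m * n * (m - 1) + h * (h - 1) * r^h))
    den <- (m * n + h) *
      (h * (1 - r^-(h - 1)) + m * r^m * (1 - r^-(m - 1))) *
      (m * r^m * (1 - r^-(m - 1)) * (1 - x^n) +
         h * (1 - r^-(h - 1)) * (r^(h + m) - x^n))
    num / den
  })
}

#' @describeIn rho-closed-forms Star of Islands in the additional limit of
#'   many islands (n -> infinity): 0 for \eqn{r <= 1}, positive above.
#' @export
rho_si_inf <- function(m, h, r) {
  m <- check_count(m, 2L, "m")
  h <- check_count(h, 2L, "h")
  check_r(r)
  out <- numeric(length(r))
  hi <- r > 1
  rr <- r[hi]
  out[hi] <- (m - 1) * (1 - rr^-1) * (1 - rr^-(h + m)) /
    (h * rr^-m * (1 - rr^-(h - 1)) + m * (1 - rr^-(m - 1)))
  out
}

#' Evaluate a fixation curve on a fitness grid
#'
#' Convenience wrapper producing `rho(r)` on a grid by one of the three
#' routes: the exact 2^N chain, a family closed form, or Monte Carlo.
#'
#' @param G a connected [weighted_graph()] (exact and Monte Carlo methods).
#' @param r_values grid of positive fitness values.
#' @param method one of `"exact"`, `"monte-carlo"`.
#' @param trials,seed Monte Carlo settings (see [simulate_fixation()]).
#' @return A data frame of class `fixation_curve` with columns `r`, `rho`,
#'   `method`.
#' @export
fixation_curve <- function(G, r_values, method = c("exact", "monte-carlo"),
                           trials = 10000L, seed = 1L) {
  method <- match.arg(method)
  check_r(r_values)
  rho <- switch(method,
    "exact" = vapply(r_values, function(r) rho_exact(G, r), numeric(1)),
    "monte-carlo" = vapply(seq_along(r_values), function(k)
      simulate_fixation(G, r_values[k], trials = trials,
                        seed = seed + k - 1L)$rho_hat, numeric(1)))
  structure(data.frame(r = r_values, rho = rho, method = method),
            class = c("fixation_curve", "data.frame"))
}
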