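#' Closed-form effective population sizes for the named graph families
#'
#' Analytic counterparts to the numeric coalescence solver. The Fan form
#' holds for any hub-edge weight `eps >= 0` (with `eps = 0` read as the
#' analytic limit); the Separated Hubs and Star of Islands forms are the
#' `eps -> 0` limits only.
#'
#' @name neff-closed-forms
#' @inheritParams graph-families
#' @return Effective population size (positive scalar).
NULL

#' @describeIn neff-closed-forms the Fan \eqn{F_{n,m}} at hub-edge weight
#'   `eps`. The second term vanishes at the isothermal point
#'   `eps = (m-1)/(nm-1)` (where `N_eff = N = nm + 1`), is positive below it
#'   (amplifier of weak selection), and tends to `nm + n - 1` as eps -> 0.
#' @export
closed_form_neff_fan <- function(n, m, eps) {
  n <- as.numeric(check_count(n, 2L, "n"))   # numeric: n may be huge (limits)
  m <- as.numeric(check_count(m, 2L, "m"))
  if (length(eps) != 1L || !is.finite(eps) || eps < 0)
    stop("`eps` must be a single nonnegative number", call. = FALSE)
  N <- n * m + 1
  num <- (m - 1 - eps * (n * m - 1)) *
    (m * (m - 1) * (n - 2) + eps * (n * m^2 + n * m - 4 * m + 2) +
       2 * eps^2 * (n * m - 1))
  den <- (m - 1 + 2 * eps) *
    (m * (m - 1) + eps * (n * m + 2 * m - 1) + eps^2 * (n * m + 1))
  N + num / den
}

#' @describeIn neff-closed-forms Separated Hubs \eqn{SH_{n,m,h}} in the
#'   eps -> 0 limit: `nm + n - 1`, independent of the number of hubs, so the
#'   ratio `N_eff / N` tends to 0 as h grows (strongest suppression) and to
#'   3/2 for `m = 2`, n -> infinity (strongest amplification).
#' @export
closed_form_neff_sh_limit <- function(n, m, h) {
  n <- as.numeric(check_count(n, 2L, "n"))
  m <- as.numeric(check_count(m, 2L, "m"))
  h <- check_count(h, 1L, "h")
  n * m + n - 1
}

#' @describeIn neff-closed-forms Star of Islands \eqn{SI_{n,m,h}} in the
#'   eps -> 0 limit; the deviation from `N = nm + h` has the sign of `m - h`.
#' @export
closed_form_neff_si_limit <- function(n, m, h) {
  n <- as.numeric(check_count(n, 2L, "n"))
  m <- as.numeric(check_count(m, 2L, "m"))
  h <- as.numeric(check_count(h, 2L, "h"))
  N <- n * m + h
  hh <- h * (h - 1)
  mm <- m * (m - 1)
  N + (m - h) * m * n * h * (hh + mm * (n - 2)) /
    ((hh + mm) * (hh + mm * n))
}

#' Isothermal point and amplification window of the Fan
#'
#' The Fan is isothermal exactly at `eps = (m-1)/(nm-1)` and amplifies weak
#' selection for all smaller positive eps. `fan_amplification_boundary()`
#' locates the root of `N_eff(eps) = N` numerically, by bisection over the
#' coalescence solver, as an independent check of the analytic boundary.
#'
#' @inheritParams graph-families
#' @param lower,upper bracket for the root (must straddle the boundary).
#' @return The boundary value of eps.
#' @export
fan_amplification_boundary <- function(n, m, lower = 0.02, upper = 0.95) {
  f <- function(eps) effective_population_size(make_fan(n, m, eps))$n_eff -
    (n * m + 1)
  stats::uniroot(f, c(lower, upper), tol = coalfix_tolerances()$root)$root
}
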