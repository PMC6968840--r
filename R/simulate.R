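#' Monte-Carlo estimate of the fixation probability
#'
#' Seeded forward simulation of the death-Birth process. Each trial starts
#' with a single mutant at a uniformly chosen vertex and runs until the
#' mutant lineage fixes or is lost. With a fixed seed the full trial
#' sequence is reproducible bit for bit.
#'
#' @param G a connected [weighted_graph()].
#' @param r mutant fitness, \eqn{r > 0}.
#' @param trials number of independent trials.
#' @param seed RNG seed.
#' @param max_steps optional per-trial step cap (default: none; absorption is
#'   almost sure on a connected graph). Capped trials are excluded from the
#'   estimate, counted in `max_steps_hit`, and flagged with a warning.
#' @return An object of class `simulation_estimate`: list with `rho_hat`,
#'   `trials`, `fixed_count`, `se` (binomial standard error), `seed`,
#'   `max_steps_hit`, and `mean_steps`.
#' @examples
#' simulate_fixation(make_cycle(6), r = 2, trials = 2000, seed = 1)
#' @export
simulate_fixation <- function(G, r, trials, seed, max_steps = NULL) {
  G <- as_weighted_graph(G)
  stop_if_disconnected(G)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive fitness value", call. = FALSE)
  trials <- check_count(trials, 1L, "trials")
  cap <- if (is.null(max_steps)) 0 else as.numeric(max_steps)
  set.seed(seed)
  out <- simulate_fixation_cpp(G$w, r, trials, cap)
  used <- trials - out$capped
  if (out$capped > 0L)
    warning(out$capped, " trial(s) hit max_steps and were excluded")
  rho_hat <- if (used > 0L) out$fixed / used else NA_real_
  structure(list(
    rho_hat = rho_hat,
    trials = trials,
    fixed_count = out$fixed,
    se = if (used > 0L) sqrt(rho_hat * (1 - rho_hat) / used) else NA_real_,
    seed = seed,
    max_steps_hit = out$capped,
    mean_steps = out$total_steps / trials
  ), class = "simulation_estimate")
}

#' @export
print.simulation_estimate <- function(x, ...) {
  cat("<simulation_estimate> rho_hat =", format(x$rho_hat, digits = 6),
      "+/-", format(x$se, digits = 3),
      "(", x$fixed_count, "/", x$trials, "trials fixed, seed", x$seed, ")\n")
  if (x$max_steps_hit > 0)
    cat("  ", x$max_steps_hit, "trials hit the step cap and were excluded\n")
  invisible(x)
}
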