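#' Write a directory of small example graphs
#'
#' Generates edge-list fixtures covering the deterministic families (complete,
#' star, cycle, Fan, Separated Hubs, Star of Islands across the three
#' qualitative parameter regimes) plus seeded random graphs. Regeneration
#' with the same seed is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the random graphs.
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  graphs <- list()
  for (N in 3:6) graphs[[paste0("complete_K", N)]] <- make_complete(N)
  for (n in 2:5) graphs[[paste0("star_S", n)]] <- make_star(n)
  for (N in 3:8) graphs[[paste0("cycle_C", N)]] <- make_cycle(N)
  for (n in 2:4) for (m in 2:3) for (eps in c(1e-6, 0.1))
    graphs[[sprintf("fan_n%d_m%d_eps%g", n, m, eps)]] <- make_fan(n, m, eps)
  # Separated Hubs / Star of Islands: one case per classification regime
  for (p in list(c(2, 2, 2), c(3, 2, 2), c(4, 2, 2)))
    graphs[[sprintf("sh_n%d_m%d_h%d", p[1], p[2], p[3])]] <-
      make_separated_hubs(p[1], p[2], p[3], eps = 0.01)
  for (p in list(c(2, 2, 3), c(2, 3, 3), c(2, 4, 3)))
    graphs[[sprintf("si_n%d_m%d_h%d", p[1], p[2], p[3])]] <-
      make_star_of_islands(p[1], p[2], p[3], eps = 0.01)
  for (k in 1:4)
    graphs[[sprintf("er_N20_k4_seed%d", k)]] <-
      make_erdos_renyi(20, 4, seed = seed + k)
  for (k in 1:3)
    graphs[[sprintf("ba_N20_m3_seed%d", k)]] <-
      make_barabasi_albert(20, 3, seed = seed + k)
  for (k in 1:3)
    graphs[[sprintf("reg3_N12_seed%d", k)]] <-
      make_random_regular(12, 3, seed = seed + k)
  files <- character(0)
  for (nm in names(graphs)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_edgelist(graphs[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}
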