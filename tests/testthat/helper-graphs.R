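# shared graph collections for the suite

# a small bag of connected graphs mixing families and random models
mixed_graph_bag <- function(n_random = 20, seed0 = 100) {
  graphs <- list(
    make_complete(4), make_complete(6),
    make_star(3), make_star(6),
    make_cycle(5), make_cycle(8),
    make_fan(2, 2, 0.5), make_fan(3, 2, 0.1), make_fan(3, 3, 1 / 4),
    make_separated_hubs(3, 2, 2, 0.2),
    make_star_of_islands(2, 3, 3, 0.1)
  )
  for (s in seq_len(n_random)) {
    graphs <- c(graphs, list(switch(1 + s %% 3,
      make_erdos_renyi(10 + s, 4, seed = seed0 + s),
      make_barabasi_albert(10 + s, 3, seed = seed0 + s),
      make_random_regular(10 + s + (s %% 2), 3, seed = seed0 + s))))
  }
  graphs
}

# isothermal examples: cycles, complete graphs, random regular, tuned Fans
isothermal_bag <- function() {
  graphs <- list(make_complete(4), make_complete(7),
                 make_cycle(5), make_cycle(9))
  for (s in 1:4)
    graphs <- c(graphs, list(make_random_regular(10 + 2 * s, 3, seed = s)))
  for (n in 2:5) for (m in 2:4)
    graphs <- c(graphs, list(make_fan(n, m, (m - 1) / (n * m - 1))))
  graphs
}

expect_symmetric_graph <- function(G) {
  expect_identical(G$w, t(G$w))
  expect_true(all(diag(G$w) == 0))
  expect_true(all(G$w >= 0))
}
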