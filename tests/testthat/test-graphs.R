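test_that("family constructors build the documented structures", {
  k3 <- make_complete(3)
  expect_equal(weighted_degrees(k3), rep(2, 3))
  expect_equal(make_complete(2)$w, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(stationary_distribution(make_complete(5)), rep(1 / 5, 5))

  s3 <- make_star(3)
  expect_equal(weighted_degrees(s3), c(3, 1, 1, 1))
  expect_equal(make_star(2)$N, 3L)                    # path of 3 vertices
  expect_equal(stationary_distribution(make_star(9))[1], 1 / 2)

  expect_equal(make_cycle(3)$w, make_complete(3)$w)
  expect_equal(weighted_degrees(make_cycle(6)), rep(2, 6))
  expect_true(is_isothermal(make_cycle(6)))

  f <- make_fan(3, 3, 0.5)
  expect_equal(f$N, 10L)
  expect_equal(weighted_degrees(f)[2], (3 - 1) + 0.5)  # blade vertex
  expect_true(is_connected_graph(make_fan(4, 2, 1e-3)))

  sh <- make_separated_hubs(3, 2, 2, 0.1)
  expect_equal(sh$N, 8L)
  expect_equal(weighted_degrees(sh)[1], 3 * 2 * 0.1)   # hub degree = nm*eps
  expect_equal(sh$w[1, 2], 0)                          # hubs unconnected
  # h = 1 reduces exactly to the Fan
  expect_equal(make_separated_hubs(3, 2, 1, 0.25)$w, make_fan(3, 2, 0.25)$w)

  si <- make_star_of_islands(2, 3, 3, 0.1)
  expect_equal(si$N, 9L)
  expect_equal(weighted_degrees(si)[1], (3 - 1) + 2 * 3 * 0.1)
  expect_equal(si$w[1, 2], 1)                          # hub island is complete

  for (G in list(k3, s3, f, sh, si)) expect_symmetric_graph(G)
})

test_that("constructors reject invalid sizes and parameters", {
  expect_error(make_complete(1), "integer >= 2")
  expect_error(make_star(1), "integer >= 2")
  expect_error(make_cycle(2), "integer >= 3")
  expect_error(make_fan(3, 2, 0), "positive")
  expect_error(make_separated_hubs(3, 2, 2, -0.1), "positive")
  expect_error(make_erdos_renyi(4, 5, seed = 1), "probability")
  expect_error(make_barabasi_albert(4, 3, seed = 1), "m_links \\+ 2")
  expect_error(make_random_regular(5, 3, seed = 1), "infeasible")
  expect_error(weighted_graph(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(weighted_graph(diag(2)), "self-loops")
})

test_that("random generators are seeded, connected, and structurally correct", {
  g1 <- make_erdos_renyi(20, 4, seed = 42)
  g2 <- make_erdos_renyi(20, 4, seed = 42)
  expect_identical(g1$w, g2$w)
  expect_true(is_connected_graph(g1))

  # N = <k>+1 forces p = 1, the complete graph
  expect_equal(make_erdos_renyi(5, 4, seed = 1)$w, make_complete(5)$w)
  expect_equal(make_barabasi_albert(5, 3, seed = 1)$w, make_complete(5)$w)

  ba <- make_barabasi_albert(50, 3, seed = 7)
  expect_true(min(weighted_degrees(ba)) >= 3)
  expect_identical(ba$w, make_barabasi_albert(50, 3, seed = 7)$w)

  for (s in 1:20) {
    rg <- make_random_regular(12, 3, seed = s)
    expect_equal(weighted_degrees(rg), rep(3, 12))
  }
  # empirical ER mean degree: binomial sampling check over 60 seeds
  degs <- unlist(lapply(1:60, function(s)
    weighted_degrees(make_erdos_renyi(20, 4, seed = s, require_connected = FALSE))))
  se <- sqrt(4 * (1 - 4 / 19) / length(degs))
  expect_lt(abs(mean(degs) - 4), 3 * se)
})

test_that("walk quantities satisfy their probability contracts", {
  for (G in mixed_graph_bag(n_random = 6)) {
    p <- step_probabilities(G)
    expect_equal(rowSums(p), rep(1, G$N), tolerance = 1e-12)
    pi_i <- stationary_distribution(G)
    expect_equal(sum(pi_i), 1, tolerance = 1e-12)
    mom <- degree_moments(G)
    expect_gte(mom$mu2, mom$mu1^2)
  }
  # Fan isothermal point, all (n, m) in {2..5}^2
  for (n in 2:5) for (m in 2:5)
    expect_true(is_isothermal(make_fan(n, m, (m - 1) / (n * m - 1)), tol = 1e-12))
})

test_that("edge-list I/O round-trips and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  for (G in list(make_complete(4), make_fan(3, 2, 0.1),
                 make_erdos_renyi(15, 4, seed = 3))) {
    write_edgelist(G, f)
    expect_equal(read_edgelist(f)$w, G$w)
  }
  writeLines("0\t0\t1.0", f)
  expect_error(read_edgelist(f), "self-loop")
  writeLines(c("0\t1\t1.0", "1\t0\t1.0", "1\t2\t2.0"), f)
  expect_equal(read_edgelist(f)$w[1, 2], 1)            # deduplicated
  writeLines(c("0\t1\t1.0", "1\t0\t2.0"), f)
  expect_error(read_edgelist(f), "conflicting")
  writeLines("0\t1\t-1.0", f)
  expect_error(read_edgelist(f), "nonnegative")
  # JSON export carries the same edges
  js <- jsonlite::fromJSON(graph_to_json(make_star(3)))
  expect_equal(js$N, 4)
  expect_equal(nrow(js$edges), 3)
})

test_that("fixture generation is deterministic and readable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixtures(d1, seed = 5)
  f2 <- make_fixtures(d2, seed = 5)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  g <- read_edgelist(file.path(d1, "si_n2_m3_h3.tsv"))
  expect_equal(g$N, 9L)
})
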