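test_that("coalescence times match hand-solved small cases", {
  # K_N: single unknown tau = 1 + ((N-2)/(N-1)) tau  =>  tau = N - 1
  for (N in c(3, 5, 8)) {
    tau <- coalescence_times(make_complete(N))
    expect_equal(tau[upper.tri(tau)], rep(N - 1, N * (N - 1) / 2),
                 tolerance = 1e-10)
    expect_equal(remeeting_times(make_complete(N), tau), rep(N, N),
                 tolerance = 1e-10)
  }
  # C_4 reduces to two unknowns: adjacent a = 1 + b/2, antipodal b = 1 + a,
  # giving a = 3, b = 4
  tau <- coalescence_times(make_cycle(4))
  expect_equal(tau[1, 2], 3, tolerance = 1e-10)
  expect_equal(tau[1, 3], 4, tolerance = 1e-10)
  expect_equal(tau[1, 4], 3, tolerance = 1e-10)
  expect_identical(diag(tau), rep(0, 4))
  expect_error(coalescence_times(weighted_graph(matrix(
    c(0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 0), 4, 4))), "connected")
})

test_that("star remeeting times and N_eff equal 4n/(n+1)", {
  for (n in c(2, 5, 9)) {
    res <- effective_population_size(make_star(n))
    expect_equal(unname(res$tau_remeet), rep(4 * n / (n + 1), n + 1),
                 tolerance = 1e-9)
    expect_equal(res$n_eff, 4 * n / (n + 1), tolerance = 1e-9)
    expect_equal(classify_weak(make_star(n)), "suppressor-of-weak-selection")
  }
})

test_that("solver residual, Kac identity and covariance identity hold on a mixed bag", {
  for (G in mixed_graph_bag(n_random = 10)) {
    res <- effective_population_size(G)
    expect_lt(attr(res$tau_pair, "residual"), 1e-9)
    expect_lt(res$kac_residual, 1e-8)
    expect_gt(res$n_eff, 0)
    expect_true(all(res$tau_pair[upper.tri(res$tau_pair)] >= 1))
    expect_lt(covariance_identity_residual(G, res)$residual, 1e-10)
  }
})

test_that("isothermal graphs have N_eff = N and classify as neither", {
  for (G in isothermal_bag()) {
    res <- effective_population_size(G)
    expect_lt(abs(res$n_eff - G$N), 1e-8)
    expect_equal(classify_weak(G), "neither")
  }
})

test_that("weak-selection expansion has the documented slope and intercept", {
  ws <- weak_selection_fixation(make_complete(6))
  expect_equal(ws$slope, (6 - 2) / (2 * 6), tolerance = 1e-10)
  expect_equal(ws$rho_at(0), 1 / 6)
  # star S_n: expansion 1/N + delta (N-2)/N^2
  for (n in c(3, 6)) {
    ws <- weak_selection_fixation(make_star(n))
    N <- n + 1
    expect_equal(ws$slope, (N - 2) / N^2, tolerance = 1e-9)
  }
  # covariance sign tracks the weak classification
  expect_gt(covariance_identity_residual(make_star(5))$covariance, 0)
  expect_lt(covariance_identity_residual(make_fan(4, 2, 1e-3))$covariance, 0)
})

test_that("closed-form N_eff expressions agree with the numeric solver", {
  # Fan at exact eps
  for (n in 2:4) for (m in 2:3) for (eps in c(0.05, 0.2)) {
    expect_equal(closed_form_neff_fan(n, m, eps),
                 effective_population_size(make_fan(n, m, eps))$n_eff,
                 tolerance = 1e-8)
  }
  # isothermal point gives exactly N; eps -> 0 limit gives nm + n - 1
  expect_equal(closed_form_neff_fan(3, 2, 1 / 5), 7, tolerance = 1e-12)
  expect_equal(closed_form_neff_fan(3, 2, 0), 3 * 2 + 3 - 1)
  # SH limit: independent of h, matches small-eps solver to O(eps)
  expect_equal(closed_form_neff_sh_limit(3, 2, 2), 8)
  expect_equal(closed_form_neff_sh_limit(3, 2, 6), 8)
  expect_equal(
    effective_population_size(make_separated_hubs(3, 2, 2, 1e-6))$n_eff, 8,
    tolerance = 1e-3)
  # SI limit: m = h gives exactly N; sign of n_eff - N is sign of m - h
  expect_equal(closed_form_neff_si_limit(2, 3, 3), 9)
  expect_gt(closed_form_neff_si_limit(2, 4, 3), 2 * 4 + 3)
  expect_lt(closed_form_neff_si_limit(2, 2, 3), 2 * 2 + 3)
  expect_equal(
    closed_form_neff_si_limit(2, 4, 3),
    effective_population_size(make_star_of_islands(2, 4, 3, 1e-6))$n_eff,
    tolerance = 1e-3)
})

test_that("mean-field approximation is bounded by N with equality iff isothermal", {
  for (G in mixed_graph_bag(n_random = 8)) {
    mf <- meanfield_neff(G)
    expect_lte(mf, G$N + 1e-10)
    if (is_isothermal(G)) expect_equal(mf, G$N, tolerance = 1e-10)
    else expect_lt(mf, G$N - 1e-10)
  }
  # star: mu1 = 2n/(n+1), mu2 = n  =>  N mu1^2/mu2 = 4n/(n+1)
  n <- 5
  expect_equal(meanfield_neff(make_star(n)), 4 * n / (n + 1), tolerance = 1e-12)
  expect_equal(er_meanfield_ratio(20, 4 / 19), (19 * 4 / 19) / (18 * 4 / 19 + 1))
  expect_equal(er_meanfield_ratio(20, 1), 1)
})

test_that("N_eff gradient matches finite differences and drives amplifier construction", {
  # uniform scaling leaves pi unchanged: zero gradient
  g <- make_cycle(6)
  all_edges <- which(upper.tri(g$w) & g$w > 0, arr.ind = TRUE)
  expect_equal(neff_gradient(g, cbind(all_edges, 1)), 0, tolerance = 1e-10)

  # single-edge decrease on C_6: analytic gradient vs central difference
  grad <- neff_gradient(g, cbind(1, 2, -1))
  h <- 1e-5
  fd <- vapply(c(h, -h), function(d) {
    w <- g$w; w[1, 2] <- w[1, 2] - d; w[2, 1] <- w[1, 2]
    effective_population_size(weighted_graph(w))$n_eff
  }, numeric(1))
  expect_equal(grad, (fd[1] - fd[2]) / (2 * h), tolerance = 1e-3)
  expect_error(neff_gradient(make_star(4), cbind(1, 2, -1)), "isothermal")

  # perturbing a 3-regular graph at the max remeeting-time vertex amplifies
  out <- construct_amplifier(make_random_regular(12, 3, seed = 5), eps = 0.5)
  expect_gt(out$gradient, 0)
  expect_true(out$amplifier)
  expect_equal(out$result$n_eff,
               effective_population_size(out$graph)$n_eff, tolerance = 1e-12)
  # eps = 0 leaves the isothermal graph unchanged
  out0 <- construct_amplifier(make_cycle(8), eps = 0)
  expect_equal(out0$result$n_eff, 8, tolerance = 1e-8)
})
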