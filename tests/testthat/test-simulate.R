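test_that("the ODE right-hand side assembles production minus consumption times X", {
  # no biomass, no transformation
  net <- synthetic_truth_network(2)
  conc <- net$compounds$initial
  expect_equal(unname(network_rhs(net, conc, 0)), rep(0, 12))

  # 1:1 molar transfer down a two-compound chain
  ch <- chain_network(kA = 2e-3)
  d <- network_rhs(ch, c(100, 0), X = 50)
  expect_equal(unname(d), c(-2e-3 * 100 * 50, 2e-3 * 100 * 50))
  expect_equal(sum(d), 0)

  # acid node fed by amide, aldehyde and CoA branches under channeling,
  # assembled by hand edge by edge from Table-style initial concentrations
  k <- setNames(rep(1e-4, 12), names(network_params(case_network(2))))
  k[c("k[p-hydroxybenzamide]", "k[p-hydroxybenzaldehyde]",
      "k[p-coumaroyl-CoA]", "k[p-hydroxybenzoic acid]")] <-
    c(2e-4, 3.5e-4, 2.5e-4, 6e-5)
  net <- set_network_params(case_network(2), k)
  d <- network_rhs(net, net$compounds$initial, X = 1)
  expected_phb <- 2e-4 * 20.6 + 3.5e-4 * 59.4 + 2.5e-4 * 0 - 6e-5 * 47.8
  expect_equal(d[["p-hydroxybenzoic acid"]], expected_phb)

  expect_error(network_rhs(net, c(1, 2), 1), "12 elements")
  expect_error(network_rhs(net, rep(-1, 12), 1), ">= 0")
})

test_that("zero rate constants freeze the system", {
  net <- case_network(3)
  net$reactions$k <- 0
  traj <- simulate_network(net, synthetic_truth_biomass(), t_end = 48, dt = 1)
  m <- trajectory_matrix(traj)
  expect_true(all(abs(sweep(m, 2, m[1, ])) == 0))
})

test_that("Euler matches the closed-form exponential under constant biomass", {
  # kX = 0.05/h: relative error < 1e-3 at t = 50 h with dt = 0.01 h
  k <- 1e-4; X0 <- 500
  net <- decay_network(k)
  traj <- simulate_network(net, X0, t_end = 50, dt = 0.01)
  m <- trajectory_matrix(traj)
  exact <- 100 * exp(-k * X0 * 50)
  expect_lt(abs(m[nrow(m), 1] - exact) / exact, 1e-3)
  # first-order convergence: halving dt roughly halves the error
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    m <- trajectory_matrix(simulate_network(net, X0, t_end = 50, dt = dt))
    abs(m[nrow(m), 1] - exact)
  }, numeric(1))
  expect_equal(err[1] / err[2], 2, tolerance = 0.1)
  expect_equal(err[2] / err[3], 2, tolerance = 0.1)
})

test_that("sink-free networks conserve total molar concentration at every step", {
  for (cs in c(1, 2, 5)) {
    net <- sink_free_case(cs)
    traj <- simulate_network(net, synthetic_truth_biomass(), t_end = 192, dt = 1)
    totals <- rowSums(trajectory_matrix(traj))
    expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-12)
  }
})

test_that("trajectories stay non-negative and clipping is reported", {
  traj <- simulate_network(synthetic_truth_network(5), synthetic_truth_biomass(),
                           t_end = 192, dt = 1)
  expect_true(all(trajectory_matrix(traj) >= 0))
  # absurdly fast reaction overshoots at dt = 1 and gets clipped
  fast <- decay_network(k = 0.05)
  expect_warning(traj <- simulate_network(fast, 500, t_end = 10, dt = 1),
                 "clipped")
  expect_true(all(trajectory_matrix(traj) >= 0))
})

test_that("raising a competitive inhibitor never accelerates the inhibited compound", {
  base <- synthetic_truth_network(3)
  hi <- base
  hi$compounds$initial[hi$compounds$compound == "p-coumaroyl amide"] <- 4000
  bm <- synthetic_truth_biomass()
  fa_base <- trajectory_matrix(simulate_network(base, bm, 192, dt = 1))[, "feruloyl amide"]
  fa_hi <- trajectory_matrix(simulate_network(hi, bm, 192, dt = 1))[, "feruloyl amide"]
  expect_true(all(fa_hi >= fa_base - 1e-9))
})

test_that("the compiled integrator agrees with a stiff reference solver", {
  skip_if_not_installed("deSolve")
  net <- synthetic_truth_network(5)
  bm <- synthetic_truth_biomass()
  rhs <- function(t, y, parms) {
    list(unname(network_rhs(net, pmax(y, 0), gompertz_biomass(t, bm))))
  }
  ref <- deSolve::lsoda(net$compounds$initial, times = seq(0, 96, by = 12),
                        func = rhs, parms = NULL, rtol = 1e-8, atol = 1e-8)
  traj <- simulate_network(net, bm, t_end = 96, dt = 0.01)
  m <- trajectory_matrix(traj)
  ours <- m[match(seq(0, 96, by = 12), attr(traj, "times")), ]
  expect_equal(unname(ours), unname(ref[, -1]), tolerance = 1e-3)
})
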