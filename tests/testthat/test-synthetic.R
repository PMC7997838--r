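test_that("noiseless generation is an exact passthrough of the fine simulation", {
  sp <- synthetic_spec(synthetic_truth_network(2), noise = "none", seed = 1)
  ds <- generate_dataset(sp)
  expect_identical(ds$observations, ds$truth$noiseless)
  expect_equal(ds$observations$time_h, seq(0, 192, by = 12))
  # initial concentrations are the hydrolysate values
  expect_equal(ds$observations$`p-coumaroyl amide`[1], 2090)
  expect_equal(ds$observations$`feruloyl amide`[1], 1040)
  expect_equal(ds$observations$`p-coumaric acid`[1], 446)
  # only measurable compounds are observed
  expect_false(any(c("p-coumaroyl-CoA", "feruloyl-CoA") %in% names(ds$observations)))
})

test_that("the seed fully determines the noise draws", {
  mk <- function(seed) generate_dataset(synthetic_spec(
    synthetic_truth_network(2), seed = seed))
  a <- mk(7); b <- mk(7); c <- mk(8)
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations, c$observations))
  expect_true(all(as.matrix(a$observations) >= 0))
})

test_that("proportional noise reproduces the nominal CV", {
  # repeat draws of one large value (noise floor off) and check the sample CV
  net <- synthetic_truth_network("syringyl")
  draws <- vapply(1:1000, function(s) {
    sp <- synthetic_spec(net, duration = 24, sampling_times = c(0, 24),
                         noise = "gaussian_proportional", noise_cv = 0.05,
                         noise_floor = 0, seed = s, fine_dt = 0.5)
    generate_dataset(sp)$observations$syringamide[2]
  }, numeric(1))
  cv <- stats::sd(draws) / mean(draws)
  expect_gt(cv, 0.045)
  expect_lt(cv, 0.055)
})

test_that("channeling truth shows the observed qualitative signatures", {
  # zero terminal consumption of vanillic acid -> monotone accumulation
  net <- synthetic_truth_network(2)
  net$reactions$k[net$reactions$substrate == "vanillic acid"] <- 0
  m <- trajectory_matrix(simulate_network(net, synthetic_truth_biomass(),
                                          t_end = 192, dt = 1))
  van <- m[, "vanillic acid"]
  expect_true(all(diff(van) >= 0))
  # with a brisk positive consumption it peaks and declines instead
  net2 <- set_network_params(synthetic_truth_network(2),
                             c("k[vanillic acid]" = 3e-4))
  van2 <- trajectory_matrix(simulate_network(net2, synthetic_truth_biomass(),
                                             t_end = 192, dt = 1))[, "vanillic acid"]
  expect_gt(max(van2), van2[1])
  expect_lt(van2[length(van2)], max(van2) * 0.95)
  # CoA intermediates rise then fall; aldehydes only fall under channeling
  coa <- m[, "p-coumaroyl-CoA"]
  peak <- which.max(coa)
  expect_gt(peak, 1)
  expect_lt(peak, length(coa))
  expect_lt(coa[length(coa)], max(coa) / 2)
  expect_true(all(diff(m[, "p-hydroxybenzaldehyde"]) <= 1e-12))
  expect_true(all(diff(m[, "vanillin"]) <= 1e-12))
})

test_that("more methoxy substitutions means slower disappearance", {
  bm <- synthetic_truth_biomass()
  half_time <- function(trace, times) times[which(trace <= trace[1] / 2)[1]]
  m_hg <- trajectory_matrix(simulate_network(synthetic_truth_network(2), bm,
                                             t_end = 192, dt = 1))
  m_s <- trajectory_matrix(simulate_network(synthetic_truth_network("syringyl"),
                                            bm, t_end = 192, dt = 1))
  t_grid <- seq(0, 192, by = 1)
  t_h <- half_time(m_hg[, "p-hydroxybenzaldehyde"], t_grid)
  t_g <- half_time(m_hg[, "vanillin"], t_grid)
  t_s <- half_time(m_s[, "syringaldehyde"], t_grid)
  expect_lt(t_h, t_g)
  expect_lt(t_g, t_s)
})

test_that("the benchmark suite covers the four standard scenarios", {
  suite <- benchmark_suite(2)
  expect_named(suite, c("recovery", "discrimination", "s_chain", "biomass"))
  expect_equal(suite$recovery$spec$noise, "none")
  rx <- suite$discrimination$spec$network$reactions
  inh <- rx[rx$law == "inhibited", ]
  expect_equal(nrow(inh), 7)
  expect_equal(sum(inh$substrate == inh$inhibitor), 4)
  # strong inhibition: factors well below the initial H amide concentration
  expect_true(all(inh$k_i <= 200))
  expect_s3_class(suite$biomass$dataset$biomass_obs, "tbl_df")
})
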