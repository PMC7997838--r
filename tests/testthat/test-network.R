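test_that("case networks have the documented topology and rate-law structure", {
  expected_inhibited <- c(0, 0, 3, 8, 7)
  for (cs in 1:5) {
    net <- case_network(cs)
    expect_length(validate_network(net), 0)
    expect_equal(nrow(net$compounds), 12)
    expect_equal(sum(net$compounds$measurable), 10)
    expect_equal(sum(net$reactions$law == "inhibited"), expected_inhibited[cs])
    expect_false(any(net$compounds$measurable[
      net$compounds$compound %in% c("p-coumaroyl-CoA", "feruloyl-CoA")]))
    # unmeasured CoA intermediates start at zero
    expect_equal(net$compounds$initial[!net$compounds$measurable], c(0, 0))
  }
  rx1 <- case_network(1)$reactions
  expect_equal(rx1$product[rx1$substrate == "p-coumaroyl-CoA"], "p-hydroxybenzaldehyde")
  expect_equal(rx1$product[rx1$substrate == "feruloyl-CoA"], "vanillin")
  rx2 <- case_network(2)$reactions
  expect_equal(rx2$product[rx2$substrate == "p-coumaroyl-CoA"], "p-hydroxybenzoic acid")
  expect_equal(rx2$product[rx2$substrate == "feruloyl-CoA"], "vanillic acid")
})

test_that("cases 2-5 share topology and differ only in rate-law assignments", {
  topo <- function(cs) {
    rx <- case_network(cs)$reactions
    rx[order(rx$substrate), c("substrate", "product")]
  }
  for (cs in 3:5) expect_equal(topo(cs), topo(2))
})

test_that("case 3 inhibits the guaiacyl steps by their p-hydroxyphenyl analogs", {
  rx <- case_network(3)$reactions
  inh <- rx[rx$law == "inhibited", ]
  expect_setequal(inh$substrate, c("feruloyl amide", "ferulic acid", "feruloyl-CoA"))
  expect_equal(inh$inhibitor[match(c("feruloyl amide", "ferulic acid", "feruloyl-CoA"),
                                   inh$substrate)],
               c("p-coumaroyl amide", "p-coumaric acid", "p-coumaroyl-CoA"))
  # vanillic acid consumption stays first-order in cases 3 and 5
  for (cs in c(3, 5)) {
    rx <- case_network(cs)$reactions
    expect_equal(rx$law[rx$substrate == "vanillic acid"], "first_order")
  }
})

test_that("cases 4 and 5 self-inhibit the documented compounds", {
  rx4 <- case_network(4)$reactions
  self4 <- rx4[rx4$law == "inhibited", ]
  expect_equal(self4$inhibitor, self4$substrate)
  expect_setequal(self4$substrate,
                  c("p-coumaroyl amide", "p-coumaric acid", "p-coumaroyl-CoA",
                    "p-hydroxybenzoic acid", "feruloyl amide", "ferulic acid",
                    "feruloyl-CoA", "vanillic acid"))
  rx5 <- case_network(5)$reactions
  inh5 <- rx5[rx5$law == "inhibited", ]
  self5 <- inh5[inh5$substrate == inh5$inhibitor, ]
  comp5 <- inh5[inh5$substrate != inh5$inhibitor, ]
  expect_equal(nrow(self5), 4)
  expect_equal(nrow(comp5), 3)
  expect_true(all(self5$substrate %in%
                    c("p-coumaroyl amide", "p-coumaric acid", "p-coumaroyl-CoA",
                      "p-hydroxybenzoic acid")))
})

test_that("syringyl and side networks match their definitions", {
  s <- syringyl_network()
  expect_equal(nrow(s$compounds), 3)
  expect_equal(nrow(s$reactions), 3)
  expect_equal(nrow(s$free_parameters), 3)
  expect_true(all(s$reactions$law == "first_order"))
  ini <- setNames(s$compounds$initial, s$compounds$compound)
  expect_equal(ini[["syringamide"]], 32.6)
  expect_equal(ini[["syringaldehyde"]], 5.8)
  expect_equal(ini[["syringic acid"]], 6.9)

  b <- side_network("benzoic")
  expect_equal(nrow(b$compounds), 1)
  expect_equal(nrow(b$reactions), 1)
  expect_equal(b$compounds$initial, 160)

  v <- side_network("vanillic_to_pca")
  expect_equal(nrow(v$compounds), 2)
  expect_equal(nrow(v$reactions), 2)
  expect_equal(v$compounds$initial[v$compounds$compound == "protocatechuic acid"], 6.0)

  expect_error(side_network("nope"))
  expect_error(case_network(9), "case_id")
})

test_that("validate_network reports violations instead of throwing", {
  net <- case_network(2)
  # unresolved substrate name
  bad <- net
  bad$reactions$substrate[1] <- "X"
  expect_length(grep("substrate not in compounds", validate_network(bad)), 1)
  # two consuming reactions for one compound
  bad <- net
  bad$reactions$substrate[2] <- bad$reactions$substrate[1]
  expect_length(grep("consuming", validate_network(bad)), 1)
  # inhibited law without k_i
  bad <- case_network(3)
  bad$reactions$k_i[bad$reactions$law == "inhibited"][1] <- NA
  expect_length(grep("k_i", validate_network(bad)), 1)
  # cycle
  bad <- net
  bad$reactions$product[bad$reactions$substrate == "p-hydroxybenzoic acid"] <-
    "p-coumaroyl amide"
  expect_length(grep("cycle", validate_network(bad)), 1)
  # negative initial concentration
  bad <- net
  bad$compounds$initial[1] <- -1
  expect_length(grep("initial", validate_network(bad)), 1)
})

test_that("free parameters can be read and written by name", {
  net <- case_network(5)
  p <- network_params(net)
  expect_length(p, 12 + 7)
  expect_true(all(startsWith(names(p), "k")))
  p2 <- p
  p2[["k[ferulic acid]"]] <- 42
  p2[["k_i[ferulic acid]"]] <- 7
  net2 <- set_network_params(net, p2)
  expect_equal(network_params(net2), p2)
  expect_error(set_network_params(net, c("k[unobtainium]" = 1)), "no reaction")
})
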