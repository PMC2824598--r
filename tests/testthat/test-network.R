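test_that("network variants have the documented species and reaction counts", {
  net_s <- simple_net()
  expect_equal(net_s$n_species, 14L)
  expect_equal(net_s$n_reactions, 33L)
  expect_true(all(vapply(net_s$reactions, function(r) r$id, 1L) <= 33L))

  net_f <- full_net()
  expect_equal(net_f$n_species, 16L)
  expect_equal(net_f$n_reactions, 38L)
  ids <- vapply(net_f$reactions, function(r) r$id, 1L)
  expect_false(33L %in% ids)  # direct Mdm2 production is simple-only
  expect_true(all(34:39 %in% ids))

  net_d <- simple_net(delay_on = TRUE)
  expect_equal(net_d$delays[vapply(net_d$reactions, function(r) r$id, 1L) == 33L], 50)
  expect_identical(net_d$stoichiometry, net_s$stoichiometry)

  expect_error(build_network("full", delay_on = TRUE), "simple")
  expect_error(build_network("odd"))
})

test_that("rhs matches the brute-force stoichiometry oracle on random states", {
  for (variant in c("simple", "full")) {
    net <- build_network(variant)
    for (lab in c("col5", "col8")) {
      k <- load_parameter_set(lab)$k
      set.seed(7)
      for (i in 1:50) {
        x <- runif(net$n_species, 0, 2)
        expect_equal(network_rhs(x, k, net), brute_force_rhs(x, k, net),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("all-zero state leaves only zero-order production fluxes", {
  net <- simple_net()
  p <- load_parameter_set("col4")
  d <- unname(network_rhs(rep(0, 14), p$k, net))
  expect_equal(d[1], 0.05)               # basal p53 production k1
  expect_equal(d[3], unname(p$k[["k6"]]))   # basal Mdm2 production
  expect_equal(d[5], unname(p$k[["k15"]]))  # basal MdmX production
  expect_true(all(d[-c(1, 3, 5)] == 0))
})

test_that("promoter moiety is conserved by every reaction", {
  for (variant in c("simple", "full")) {
    net <- build_network(variant)
    prom <- if (variant == "simple") c(13, 14) else c(13, 14, 16)
    expect_true(all(colSums(net$stoichiometry[prom, , drop = FALSE]) == 0))
    # and hence the summed derivative vanishes for any state
    set.seed(1)
    x <- runif(net$n_species)
    d <- network_rhs(x, load_parameter_set(
      if (variant == "simple") "col5" else "col8")$k, net)
    expect_equal(sum(d[prom]), 0, tolerance = 1e-14)
  }
})

test_that("p53/Mdm2/MdmX moieties are conserved by pure binding dynamics", {
  # all production and degradation off: subunit-weighted totals constant
  net <- full_net()
  k <- load_parameter_set("col8")$k
  k[c("k1", "k2", "k5", "k6", "k7", "k10", "k13", "k14", "k15", "k16",
      "k19", "k22", "k33", "k36", "k37", "k38")] <- 0
  set.seed(3)
  y0 <- runif(16, 0, 0.5)
  out <- integrate_network(y0, k, net, seq(0, 500, by = 50))
  tr <- structure(list(times = out[, 1], states = out[, -1],
                       variant = "full", protocol = "test",
                       units = "minutes"), class = "trajectory")
  for (m in c("p53", "Mdm2", "MdmX")) {
    tot <- total_protein(tr, m)
    expect_lt(diff(range(tot)), 1e-8 * (1 + max(tot)))
  }
})

test_that("analytic Jacobian matches finite differences", {
  net <- full_net()
  k <- load_parameter_set("col9")$k
  set.seed(11)
  for (i in 1:5) {
    x <- runif(16, 0, 1)
    expect_equal(network_jacobian(x, k, net), fd_jacobian(x, k, net),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("published parameter columns load with their printed values", {
  p4 <- load_parameter_set("col4")
  expect_equal(p4$k[["k13"]], 5.0)
  expect_equal(p4$k[["k20"]], 11.0)
  expect_equal(p4$variant, "simple")
  expect_true(all(c("k3", "k6", "k15") %in% names(p4$scan)))

  p5 <- load_parameter_set("col5")
  expect_equal(p5$k[["k15"]], 0)
  expect_equal(p5$k[["k14"]], 0.1)
  expect_equal(p5$k[["k33"]], 0.1)

  p8 <- load_parameter_set("col8")
  expect_equal(p8$k[["k38"]], 3.708)
  expect_equal(p8$k[["k37"]], 5.551e-2)
  expect_equal(p8$k[["k3"]], 1.578e-2)
  expect_equal(p8$k1_predamage, 0.003)
  expect_equal(p8$k1_postdamage, 0.01)
  expect_equal(p8$variant, "full")

  p6 <- load_parameter_set("col6")
  expect_equal(p6$k[["k33"]], 40)
  expect_equal(p6$delay, 50)

  expect_error(load_parameter_set("col99"), "unknown")
  # simple-variant sets have no full-model reactions parameterized
  for (lab in c("col4", "col5", "col6", "col7"))
    expect_true(all(load_parameter_set(lab)$k[c("k34", "k35", "k36",
                                                "k37", "k38")] == 0))
})

test_that("search-stage constraints tie the documented symbols", {
  base <- update_k(load_parameter_set("col8"), k2 = 0.004, k13 = 2.5,
                   k3 = 1, k4 = 0.3)
  s1 <- apply_search_constraints(1, base)
  expect_equal(s1$k[["k5"]], 0.004)
  expect_equal(s1$k[["k7"]], 0.004)
  expect_equal(s1$k[["k14"]], 0.5)
  expect_equal(s1$k[["k8"]], 1)
  expect_equal(s1$k[["k9"]], 0.02)
  expect_equal(s1$k[["k4"]], 0.02)

  s2 <- apply_search_constraints(2, base)
  expect_equal(unname(s2$k[c("k10", "k17")]), c(1, 1))
  expect_equal(unname(s2$k[c("k4", "k9", "k18")]), rep(0.02, 3))
  expect_error(apply_search_constraints(3, base), "stage")
})
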