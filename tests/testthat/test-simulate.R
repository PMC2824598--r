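test_that("pre-equilibration handles the empty system and matches long integration", {
  net <- simple_net()
  # all production off: steady state is the bare promoter
  p0 <- update_k(load_parameter_set("col4"), k1 = 0, k6 = 0, k15 = 0)
  st <- pre_equilibrate(p0, net)
  expect_equal(unname(st["x13"]), 1)
  expect_equal(max(abs(st[-13])), 0)

  # two-method oracle: structural reduction vs long stiff integration
  p <- update_k(load_parameter_set("col4"), k6 = 0.05, k15 = 0)
  st1 <- pre_equilibrate(p, net)
  k <- phase_rates(p, damage = FALSE)
  out <- integrate_network(default_initial_state(net, 1), k, net,
                           c(0, 5e5))
  expect_equal(unname(st1), unname(out[2, -1]), tolerance = 1e-8)

  # full fitted set: residual criterion holds
  p8 <- load_parameter_set("col8")
  netf <- full_net()
  st8 <- pre_equilibrate(p8, netf)
  k8 <- phase_rates(p8, damage = FALSE)
  expect_lt(max(abs(network_rhs(st8, k8, netf))),
            1e-9 * (1 + max(st8)))
  # pre-damage uses the low basal p53 production
  expect_equal(k8[["k1"]], 0.003)
})

test_that("damage runs respect the protocol and conservation laws", {
  net <- simple_net()
  p <- update_k(load_parameter_set("col4"), k6 = 0.05, k15 = 0.05)
  # no perturbation: pre-equilibrated state stays put
  tr0 <- run_damage(p, damage_protocol(phospho_rate = 0, t_end = 50,
                                       feedback_off = TRUE), net)
  expect_lt(diff(range(tr0$states[, "x14"])), 1e-8)

  # damage raises promoter occupancy from zero
  tr <- run_damage(update_k(p, k6 = 1e-3),
                   damage_protocol(phospho_rate = 0.1, t_end = 55,
                                   feedback_off = TRUE), net)
  expect_equal(tr$states[1, "x14"], 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gt(max(tr$states[, "x14"]), 1e-4)
  expect_equal(tr$units, "AU")

  # promoter conservation and nonnegativity along the trajectory
  prom_tot <- rowSums(tr$states[, c("x13", "x14")])
  expect_lt(diff(range(prom_tot)), 1e-8)
  expect_true(all(tr$states > -1e-9))
})

test_that("solver tolerance refinement leaves the early readout unchanged", {
  net <- full_net()
  p <- load_parameter_set("col8")
  a1 <- early_activity(run_damage(p, damage_protocol(), net))
  a2 <- early_activity(run_damage(p, damage_protocol(rtol = 1e-9,
                                                     atol = 1e-11), net))
  expect_lt(abs(a1 - a2) / a1, 1e-3)
})

test_that("delay variant reduces to the ODE at tau = 0 and oscillates at tau = 50", {
  net_d <- simple_net(delay_on = TRUE)
  net_s <- simple_net()
  p6 <- load_parameter_set("col6")
  prot <- damage_protocol(pre_equilibrate = FALSE, t_end = 300)
  trA <- run_delay(p6, prot, net_d, tau = 0)
  trB <- run_damage(p6, prot, net_s)
  expect_lt(max(abs(trA$states - trB$states)), 1e-6)
  expect_error(run_delay(p6, prot, net_d, tau = -1), "nonnegative")
  expect_error(run_delay(p6, prot, full_net(), tau = 50), "simple")

  # delayed feedback sustains oscillations without MdmX; MdmX reduces the
  # amplitude
  amp <- function(k15) {
    tr <- run_delay(update_k(p6, k15 = k15),
                    damage_protocol(pre_equilibrate = FALSE, t_end = 2500),
                    net_d, tau = 50)
    sel <- tr$times >= 1200
    (max(tr$states[sel, "x14"]) - min(tr$states[sel, "x14"])) / 2
  }
  a0 <- amp(0); a1 <- amp(0.1)
  expect_gt(a0, 0.05)
  expect_lt(a1, a0)
})

test_that("Nutlin protocol normalizes totals and raises p53", {
  net <- full_net()
  p8 <- load_parameter_set("col8")
  nl <- run_nutlin(p8, net, t_end = 720, dt = 5)
  expect_equal(unname(unlist(nl$folds[1, c("p53", "Mdm2", "MdmX")])),
               c(1, 1, 1), tolerance = 1e-9)
  expect_gt(max(nl$folds$p53), 1.05)
  expect_error(run_nutlin(p8, simple_net(), 100), "full")
})

test_that("isolated p53:Mdm2 decay follows its closed form", {
  # only dissociation and the two complex-resolving reactions active:
  # x7(t) = x7(0) exp(-(k12 + k13 + k14) t)
  net <- simple_net()
  k <- zero_rates(k12 = 0.05, k13 = 0.2, k14 = 0.03)
  y0 <- default_initial_state(net, 0); y0["x7"] <- 1
  times <- seq(0, 20, by = 1)
  out <- integrate_network(y0, k, net, times)
  expect_equal(out[, "x7"], exp(-0.28 * times), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("pulse schedules are continuous and reduce to a plain run", {
  net <- full_net()
  p8 <- load_parameter_set("col8")
  prot <- damage_protocol(pre_equilibrate = FALSE, t_end = 400)
  tr1 <- run_damage(p8, prot, net)
  pl1 <- run_pulse(p8, list(c(400, 1)), net)
  expect_equal(pl1$states, tr1$states, tolerance = 1e-8)
  expect_error(run_pulse(p8, list(), net), "empty")

  # splitting a phase in two changes nothing: the state is carried across
  # the boundary exactly (continuity of the restart)
  pl2 <- run_pulse(p8, list(c(200, 1), c(200, 1)), net)
  expect_equal(pl2$states, tr1$states, tolerance = 1e-7)
  expect_equal(unique(pl2$phase), c(1L, 2L))
})

test_that("non-MdmX species' damage-phase steady states are independent of k15", {
  net <- simple_net()
  p5 <- update_k(load_parameter_set("col5"), k3 = 0.0086851, k1 = 2)
  non_mdmx <- paste0("x", c(1, 2, 3, 4, 7, 11, 12, 13, 14))
  sts <- lapply(c(0, 0.2, 0.6), function(v) {
    p <- update_k(p5, k15 = v)
    k <- phase_rates(p, damage = TRUE)
    out <- integrate_network(default_initial_state(net, 1), k, net,
                             seq(0, 2e5, length.out = 41))
    solve_steady_state(k, net, pmax(out[41, -1], 0))
  })
  for (i in 2:3)
    expect_equal(sts[[i]][non_mdmx], sts[[1]][non_mdmx],
                 tolerance = 1e-6)
})
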