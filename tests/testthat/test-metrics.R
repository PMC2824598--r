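test_that("total protein uses subunit weights", {
  net <- full_net()
  s <- setNames(numeric(16), paste0("x", 1:16))
  s["x12"] <- 1   # p53P tetramer
  expect_equal(total_protein_state(s, "p53", net), 4)
  s2 <- setNames(numeric(16), paste0("x", 1:16))
  s2["x8"] <- 1   # Mdm2:MdmXP heterodimer
  expect_equal(total_protein_state(s2, "Mdm2", net), 1)
  expect_equal(total_protein_state(s2, "MdmX", net), 1)
  expect_equal(total_protein_state(s2, "p53", net), 0)
  expect_error(total_protein_state(s2, "p21", net))
})

test_that("early activity readouts follow the variant conventions", {
  # constant full-model series returns the constant
  tr <- structure(list(times = 0:200,
                       states = matrix(0.3, 201, 16,
                                       dimnames = list(NULL, paste0("x", 1:16))),
                       variant = "full", protocol = "t", units = "minutes"),
                  class = "trajectory")
  expect_equal(early_activity(tr), 0.3)
  tr_short <- tr; tr_short$times <- 0:100
  tr_short$states <- tr$states[1:101, ]
  expect_error(early_activity(tr_short), "window")

  # simple model with no damage input has zero activity at t = 55
  net <- simple_net()
  p <- update_k(load_parameter_set("col4"), k15 = 0)
  tr0 <- run_damage(p, damage_protocol(phospho_rate = 0, t_end = 60,
                                       feedback_off = TRUE), net)
  expect_equal(early_activity(tr0), 0, tolerance = 1e-10)

  # full model: grid maximum is stable under 10x finer output sampling
  netf <- full_net()
  p8 <- load_parameter_set("col8")
  y0 <- pre_equilibrate(p8, netf)
  a1 <- early_activity(run_damage(p8, damage_protocol(dt = 1), netf,
                                  state0 = y0))
  a2 <- early_activity(run_damage(p8, damage_protocol(dt = 0.1), netf,
                                  state0 = y0))
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("delta_A vanishes for identical arms and shows the switch-like sign structure", {
  net <- simple_net()
  p <- update_k(load_parameter_set("col4"), k3 = 0.1, k8 = 0.1, k17 = 0.1)
  expect_equal(delta_A(update_k(p, k6 = 0.01), 0, net), 0)
  # MdmX raises early activity at low Mdm2 production with tight p53:MdmX
  # binding, and lowers it at high Mdm2 with tight Mdm2:MdmX binding
  expect_gt(delta_A(update_k(p, k6 = 0.001, k25 = 1), 5, net), 0)
  expect_lt(delta_A(update_k(p, k6 = 1, k23 = 1), 5, net), 0)
  expect_error(delta_A(p, 5, net,
                       protocol = damage_protocol(feedback_off = FALSE)),
               "feedback-off")
})

test_that("delta_A is stable under solver tolerance refinement", {
  net <- simple_net()
  p <- update_k(load_parameter_set("col4"), k3 = 0.1, k8 = 0.1, k17 = 0.1,
                k6 = 0.001, k25 = 1)
  d1 <- delta_A(p, 5, net)
  d2 <- delta_A(p, 5, net,
                protocol = damage_protocol(t_end = 60, feedback_off = TRUE,
                                           rtol = 1e-10, atol = 1e-12))
  expect_lt(abs(d1 - d2) / abs(d1), 1e-5)
})

test_that("delta_M is zero for identical arms and negative in the oscillatory regime", {
  net <- simple_net()
  p5 <- update_k(load_parameter_set("col5"), k1 = 0.2, k3 = 0.0086851)
  expect_equal(delta_M(p5, 0, net, t_end = 2000, dt = 10), 0)
  dM <- delta_M(p5, 10, net, t_end = 5e4, dt = 10)
  expect_lt(dM, 0)
})

test_that("peak detection and period recovery behave on known series", {
  t <- seq(0, 3000, by = 1)
  v <- sin(2 * pi * t / 360)
  pp <- series_period(t, v)
  expect_true(pp$oscillating)
  expect_lt(abs(pp$period - 360), 1.5)

  mono <- series_period(t, t / 3000)
  expect_false(mono$oscillating)
  expect_true(is.na(mono$period))

  # programmed spacing from the synthetic generator is recovered within one
  # sample step
  tg <- make_oscillation_target(period = 360, n_peaks = 6, dt = 5)
  pg <- series_period(tg$time, tg$value, transient_frac = 0)
  expect_lt(abs(pg$period - 360), 5 + 1e-9)
})

test_that("reservoir log-ratio switches sign with Mdm2 production", {
  net <- simple_net()
  p <- update_k(load_parameter_set("col4"), k3 = 0.1, k8 = 0.1, k17 = 0.1,
                k15 = 0.05)
  rr <- reservoir_log_ratio(p, net, data.frame(k6 = c(0.001, 1)))
  expect_gt(rr$log_ratio[1], 0)   # p53:MdmX reservoir dominates
  expect_lt(rr$log_ratio[2], 0)   # Mdm2:MdmX reservoir dominates
  # symmetric binding constants at matched free-partner levels give
  # antisymmetry of the log ratio under swapping the two reservoirs' roles
  expect_equal(ncol(rr), 4)
})

test_that("effect classification flags are consistent", {
  net <- full_net()
  p9 <- load_parameter_set("col9")
  cl <- classify_effect(p9, net, k6_points = 2,
                        k15_folds = c(1, 100))
  expect_true(cl$dependency_increase)
  expect_true(cl$no_dampening)
  expect_false(cl$dampening && cl$no_dampening)
  expect_true(all(cl$late_reductions < 5))
})
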