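test_that("steady-state solver and stability handle degenerate systems", {
  net <- simple_net()
  # pure degradation of p53: eigenvalue -k2 appears in the reduced spectrum
  k <- zero_rates(k2 = 0.37)
  st <- solve_steady_state(k, net, default_initial_state(net, 1))
  expect_equal(unname(st["x13"]), 1)
  s <- stability(st, k, net)
  expect_true(any(abs(s$eigenvalues + 0.37) < 1e-12))
  expect_true(all(Re(s$eigenvalues) <= 1e-12))

  # empty-production damage-phase system: zero state with bare promoter
  p0 <- update_k(load_parameter_set("col4"), k1 = 0, k6 = 0, k15 = 0)
  k0 <- phase_rates(p0, damage = TRUE)
  set.seed(8)
  guess <- default_initial_state(net, 1) + runif(14, 0, 0.01)
  st0 <- solve_steady_state(k0, net, guess)
  expect_equal(unname(st0["x13"]), 1, tolerance = 1e-9)
  expect_lt(max(st0[-13]), 1e-9)

  expect_error(stability(runif(14, 0.5, 1),
                         load_parameter_set("col5")$k, net), "not steady")
})

test_that("long-time integration agrees with the Newton steady state in a stable regime", {
  net <- simple_net()
  p <- update_k(load_parameter_set("col5"), k3 = 0.0086851, k1 = 2)
  k <- phase_rates(p, damage = TRUE)
  out <- integrate_network(default_initial_state(net, 1), k, net,
                           seq(0, 4e5, length.out = 81))
  y_int <- pmax(out[81, -1], 0)
  st <- solve_steady_state(k, net, y_int)
  expect_equal(unname(st), unname(y_int), tolerance = 1e-6)
})

test_that("branch tracing finds a monotone steady state and paired Hopf points", {
  net <- simple_net()
  p <- update_k(load_parameter_set("col5"), k3 = 0.0086851, k15 = 0)
  grid <- 10^seq(log10(0.02), log10(2.4), length.out = 14)
  br <- trace_branch(p, net, "k1", grid)
  x14 <- br$steady_states[, "x14"]
  expect_true(all(diff(x14) > 0))  # activity rises with p53 production
  expect_equal(length(br$hopf_points), 2)
  expect_true(any(!br$stable) && any(br$stable))
  # stability flags match the leading real part
  expect_equal(br$stable, br$max_re < 0)
})

test_that("a linear-regime branch has no Hopf points", {
  net <- simple_net()
  # weak damage, no feedback: steady states stay stable along k1
  p <- update_k(load_parameter_set("col4"), k3 = 0.01, k8 = 0.01,
                k17 = 0.01, k6 = 0.05, k15 = 0)
  p$k["k33"] <- 0; p$k["k14"] <- 0
  br <- trace_branch(p, net, "k1", c(0.01, 0.05, 0.1))
  expect_length(br$hopf_points, 0)
  expect_true(all(br$stable))
})

test_that("the Lyapunov-coefficient core matches the planar closed form", {
  # random planar quadratic fields around a Hopf at the origin:
  # dx = -y + a1 x^2 + a2 xy + a3 y^2; dy = x + b1 x^2 + b2 xy + b3 y^2.
  # Guckenheimer-Holmes give the cubic normal-form coefficient
  # 16a = f_xy (f_xx + f_yy) - g_xy (g_xx + g_yy) - f_xx g_xx + f_yy g_yy
  # (pure quadratic field, omega = 1).
  set.seed(42)
  for (rep in 1:8) {
    a <- runif(3, -1, 1); b <- runif(3, -1, 1)
    A <- matrix(c(0, 1, -1, 0), 2, 2)
    jac <- function(x) A + matrix(c(2 * a[1] * x[1] + a[2] * x[2],
                                    2 * b[1] * x[1] + b[2] * x[2],
                                    a[2] * x[1] + 2 * a[3] * x[2],
                                    b[2] * x[1] + 2 * b[3] * x[2]), 2, 2)
    Bfun <- function(u, v) {
      bl <- function(ur, vr) drop((jac(ur) - A) %*% vr)
      bl(Re(u), Re(v)) - bl(Im(u), Im(v)) +
        1i * (bl(Re(u), Im(v)) + bl(Re(v), Im(u)))
    }
    lc <- lyapunov_coefficient(A, Bfun)
    f_xx <- 2 * a[1]; f_xy <- a[2]; f_yy <- 2 * a[3]
    g_xx <- 2 * b[1]; g_xy <- b[2]; g_yy <- 2 * b[3]
    gh <- (f_xy * (f_xx + f_yy) - g_xy * (g_xx + g_yy) -
             f_xx * g_xx + f_yy * g_yy) / 16
    expect_equal(sign(lc$l1), sign(gh))
    # fixed proportionality under the unit-norm eigenvector convention
    expect_equal(lc$l1 / gh, 2, tolerance = 1e-6)
  }
})

test_that("shooting solves the Hopf normal form on the correct side", {
  # polar form dr/dt = mu r + s r^3 - r^5, omega = 1: the cubic sign decides
  # where small periodic orbits live relative to the Hopf point at mu = 0
  nf <- function(mu, s) {
    derivs <- function(y) {
      r2 <- sum(y^2)
      c(mu * y[1] - y[2] + s * y[1] * r2 - y[1] * r2^2,
        y[1] + mu * y[2] + s * y[2] * r2 - y[2] * r2^2)
    }
    flow <- function(y, T) {
      unname(deSolve::lsoda(y, c(0, T), function(t, y, p) list(derivs(y)),
                            NULL, rtol = 1e-10, atol = 1e-12)[2, -1])
    }
    list(derivs = derivs, flow = flow)
  }
  probe <- function(mu, s) {
    m <- nf(mu, s)
    for (d in c(0.05, 0.12, 0.25, 0.5)) {
      po <- p53mdmx:::shoot_bvp(m$derivs, m$flow, c(d, 0), 2 * pi,
                                anchor = 2, n_trivial = 1)
      if (po$converged && abs(po$period - 2 * pi) < pi &&
          sqrt(sum(po$y0^2)) > 1e-4)
        return(po)
    }
    NULL
  }
  # supercritical: stable orbit only where the steady state is unstable
  expect_null(probe(-0.04, -1))
  sup <- probe(0.04, -1)
  expect_false(is.null(sup))
  expect_true(sup$floquet_stable)
  expect_equal(sqrt(sum(sup$y0^2)), sqrt(0.04), tolerance = 0.05)
  # subcritical: an unstable orbit exists where the steady state is stable
  sub <- probe(-0.04, 1)
  expect_false(is.null(sub))
  expect_false(sub$floquet_stable)
})

test_that("shooting reproduces a stable full-model cycle found by integration", {
  net <- full_net()
  p8 <- load_parameter_set("col8")
  tr <- run_damage(p8, damage_protocol(pre_equilibrate = FALSE,
                                       t_end = 5000, dt = 1), net)
  sel <- tr$times >= 2500
  pk <- detect_peaks(tr$times[sel], tr$states[sel, "x15"],
                     transient_frac = 0)
  T0 <- median(diff(pk$time))
  i0 <- which(tr$times == pk$time[2])
  po <- shoot_periodic(p8, net, tr$states[i0, ], T0, species = "x15")
  expect_true(po$converged)
  expect_equal(po$period, T0, tolerance = 0.02)
  expect_true(po$floquet_stable)
  # extrema of the shot orbit match the long-integration extrema
  k <- phase_rates(p8, damage = TRUE)
  orb <- integrate_network(po$y0, k, net,
                           seq(0, po$period, length.out = 300))
  v <- tr$states[sel, "x15"]
  expect_equal(max(orb[, "x15"]), max(v), tolerance = 0.01)
  expect_equal(min(orb[, "x15"]), min(v), tolerance = 0.05)
})

test_that("limit-cycle amplitude measurement converges on the fitted oscillator", {
  net <- full_net()
  p8 <- load_parameter_set("col8")
  lc <- limit_cycle(p8, net, species = "x15", t_chunk = 6000, dt = 2,
                    max_chunks = 6)
  expect_true(lc$converged)
  expect_true(lc$oscillating)
  expect_gt(lc$amplitude, 1e-4)
  expect_equal(lc$period, 283, tolerance = 0.02)
  # raising MdmX production 100-fold collapses the cycle
  lc100 <- limit_cycle(update_k(p8, k15 = p8$k[["k15"]] * 100), net,
                       species = "x15", t_chunk = 6000, dt = 2,
                       max_chunks = 6)
  expect_lt(lc100$amplitude, 0.1 * lc$amplitude)
})

test_that("MdmX production sweep locates the oscillation boundary of the fitted set", {
  net <- full_net()
  p8 <- load_parameter_set("col8")
  br <- mdmx_bifurcation(p8, net)
  k15_base <- p8$k[["k15"]]
  i_base <- which.min(abs(br$grid - k15_base))
  i_100 <- which.min(abs(br$grid - 100 * k15_base))
  expect_false(br$stable[i_base])   # oscillatory at the fitted level
  expect_true(br$stable[i_100])     # steady at 100-fold MdmX
  expect_length(br$hopf_points, 1)
  expect_true(br$hopf_points > k15_base && br$hopf_points < 100 * k15_base)

  # degenerate single-point sweep
  br1 <- trace_branch(p8, net, "k15", k15_base * 100)
  expect_length(br1$hopf_points, 0)
  expect_equal(nrow(br1$steady_states), 1)
})
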