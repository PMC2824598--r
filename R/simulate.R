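#' Default initial state
#'
#' All species at zero except the free promoter, which carries the whole
#' promoter moiety. Used for late-response runs (which start without
#' pre-equilibration) and as the starting point of pre-equilibration itself.
#'
#' @param network a [build_network()] object.
#' @param promoter_total total promoter-moiety concentration.
#' @return named state vector.
#' @export
default_initial_state <- function(network, promoter_total = 1) {
  y <- setNames(numeric(network$n_species),
                paste0("x", seq_len(network$n_species)))
  y["x13"] <- promoter_total
  y
}

# deSolve derivative and Jacobian closures for a fixed network
.ode_func <- function(network) {
  S <- network$stoichiometry
  ki <- network$k_index; ra <- network$ra; rb <- network$rb
  i1 <- which(!is.na(ra)); i2 <- which(!is.na(rb))
  function(t, y, parms) {
    v <- parms[ki]
    v[i1] <- v[i1] * y[ra[i1]]
    v[i2] <- v[i2] * y[rb[i2]]
    list(drop(S %*% v))
  }
}

.ode_jac <- function(network) {
  function(t, y, parms) network_jacobian(y, parms, network)
}

#' Integrate the network ODEs
#'
#' Thin wrapper around [deSolve::lsoda()] with the analytic mass-action
#' Jacobian supplied for stiff steps.
#'
#' @param state0 initial state (named or not, length `n_species`).
#' @param k named rate vector `k1`..`k38` (see `phase_rates`).
#' @param network a [build_network()] object.
#' @param times output time grid.
#' @param rtol,atol solver tolerances.
#' @return matrix: first column `time`, then one column per species.
#' @export
integrate_network <- function(state0, k, network, times,
                              rtol = 1e-8, atol = 1e-10,
                              maxsteps = 50000) {
  out <- deSolve::lsoda(y = unname(state0), times = times,
                        func = .ode_func(network), parms = k,
                        jacfunc = .ode_jac(network), jactype = "fullusr",
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  colnames(out) <- c("time", paste0("x", seq_len(network$n_species)))
  out
}

new_trajectory <- function(out, network, protocol, units) {
  structure(list(times = out[, "time"],
                 states = out[, -1, drop = FALSE],
                 variant = network$variant, protocol = protocol,
                 units = units),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s variant, %d time points over [%g, %g] %s (%s)\n",
              x$variant, length(x$times), min(x$times), max(x$times),
              x$units, x$protocol))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x a trajectory.
#' @param ... unused.
#' @return data frame with columns time, species, value, protocol.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  ns <- ncol(x$states)
  data.frame(time = rep(x$times, ns),
             species = rep(colnames(x$states), each = length(x$times)),
             value = as.vector(x$states),
             protocol = x$protocol, row.names = NULL)
}

#' DNA-damage protocol description
#'
#' @param phospho_rate common damage-induced phosphorylation rate assigned to
#'   `k3 = k8 = k17`; `NULL` keeps the parameter set's own values.
#' @param pre_equilibrate start from the damage-free steady state (early
#'   response) rather than the default initial state (late response).
#' @param t_end simulated duration after damage onset.
#' @param feedback_off cut the transcription feedback (`k33 = k14 = 0`), as
#'   in the early simple-model studies.
#' @param k15_factor fold-change applied to the MdmX basal production rate.
#' @param dt output sampling interval (default 1 time unit).
#' @param rtol,atol solver tolerances used for the damage run.
#' @return a `damage_protocol` list.
#' @export
damage_protocol <- function(phospho_rate = NULL, pre_equilibrate = TRUE,
                            t_end = 180, feedback_off = FALSE,
                            k15_factor = 1, dt = 1, rtol = 1e-8,
                            atol = 1e-10) {
  if (!is.null(phospho_rate) && phospho_rate < 0)
    stop("phospho_rate must be nonnegative")
  structure(list(phospho_rate = phospho_rate,
                 pre_equilibrate = pre_equilibrate, t_end = t_end,
                 feedback_off = feedback_off, k15_factor = k15_factor,
                 dt = dt, rtol = rtol, atol = atol),
            class = "damage_protocol")
}

#' Damped-Newton steady state with promoter-conservation constraint
#'
#' Solves `rhs(x) = 0` with the free-promoter equation replaced by the
#' conservation constraint (the promoter moiety makes the plain Jacobian
#' singular). Steps are damped until the residual decreases and the state
#' stays nonnegative.
#'
#' @param guess nonnegative starting state.
#' @param k rate vector.
#' @param network network object.
#' @param promoter_total conserved promoter-moiety total.
#' @param tol max-norm residual tolerance.
#' @param max_iter Newton iteration cap.
#' @return list(state, residual, converged).
#' @export
steady_state_newton <- function(guess, k, network, promoter_total = 1,
                                tol = 1e-11, max_iter = 60) {
  x <- pmax(unname(guess), 0)
  prom <- promoter_species(network)
  resid_fun <- function(x) {
    f <- network_rhs(x, k, network)
    f[13] <- sum(x[prom]) - promoter_total
    f
  }
  f <- resid_fun(x)
  scale_ok <- function(f, x) max(abs(f)) < tol * (1 + max(abs(x)))
  # the line search is unconstrained (steady states can sit on the
  # nonnegativity boundary, where a positivity-projected search jams);
  # genuinely negative solutions are rejected after convergence
  for (it in seq_len(max_iter)) {
    if (scale_ok(f, x)) break
    J <- network_jacobian(x, k, network)
    J[13, ] <- 0; J[13, prom] <- 1
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      fn <- resid_fun(x + lambda * step)
      if (max(abs(fn)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (lambda < 1e-8) break
    x <- x + lambda * step
    f <- resid_fun(x)
  }
  min_component <- min(x)
  ok_pre <- scale_ok(f, x)
  x <- pmax(x, 0)
  f <- resid_fun(x)
  # clamping round-off-scale negatives may nudge the residual slightly;
  # accept if the iterate converged on either side of the clamp
  list(state = setNames(x, paste0("x", seq_along(x))),
       residual = max(abs(f)), min_component = min_component,
       converged = (ok_pre || scale_ok(f, x)) &&
         min_component > -1e-6 * (1 + max(x)))
}

# Damage-free steady state by structural reduction. With k3 = k8 = k17 = 0
# every phosphorylated species (and everything downstream of them: dimer,
# tetramer, occupied promoter, Mdm2:MdmXP) is zero at steady state, the MdmX
# balance collapses to x5 = k15/k16, the two heterodimer reservoirs follow
# their binding equilibria, and only free p53 (x1) and free Mdm2 (x3) remain
# coupled; these are solved by a damped 2-D Newton iteration. Note the
# non-phospho steady species are independent of the MdmX level, so the
# reservoirs scale with k15 without feeding back on x1/x3.
pre_damage_steady <- function(k, network, promoter_total) {
  full <- network$variant == "full"
  c7 <- k[["k11"]] / (k[["k12"]] + k[["k13"]] + k[["k14"]])
  a1 <- k[["k11"]] - (k[["k12"]] + k[["k14"]]) * c7
  a3 <- k[["k11"]] - (k[["k12"]] + k[["k13"]]) * c7
  q  <- if (full && k[["k35"]] > 0) k[["k34"]] / k[["k35"]] else 0
  x15_of <- function(x1) {
    if (!full || k[["k37"]] <= 0) return(0)
    x13 <- promoter_total / (1 + q * x1)
    k[["k36"]] * q * x1 * x13 / k[["k37"]]
  }
  Ffun <- function(z) {
    x1 <- z[1]; x3 <- z[2]
    c(k[["k1"]] - k[["k2"]] * x1 - a1 * x1 * x3,
      k[["k6"]] - k[["k7"]] * x3 - a3 * x1 * x3 +
        k[["k38"]] * x15_of(x1))
  }
  z <- c(if (k[["k2"]] > 0) k[["k1"]] / k[["k2"]] else 0,
         if (k[["k7"]] > 0) k[["k6"]] / k[["k7"]] else 0)
  f <- Ffun(z)
  for (it in 1:200) {
    if (max(abs(f)) < 1e-13 * (1 + max(abs(z)))) break
    h <- pmax(abs(z), 1e-8) * 1e-7
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      zp <- z; zp[j] <- zp[j] + h[j]
      J[, j] <- (Ffun(zp) - f) / h[j]
    }
    step <- tryCatch(solve(J, -f), error = function(e) return(NULL))
    if (is.null(step)) break
    lambda <- 1
    repeat {
      zn <- z + lambda * step
      if (all(zn >= 0)) {
        fn <- Ffun(zn)
        if (max(abs(fn)) < max(abs(f))) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) return(NULL)
    }
    z <- z + lambda * step; f <- Ffun(z)
  }
  x1 <- z[1]; x3 <- z[2]
  y <- setNames(numeric(network$n_species),
                paste0("x", seq_len(network$n_species)))
  x5 <- if (k[["k15"]] == 0) 0 else {
    if (k[["k16"]] <= 0) return(NULL)
    k[["k15"]] / k[["k16"]]
  }
  y["x1"] <- x1; y["x3"] <- x3; y["x5"] <- x5
  y["x7"] <- c7 * x1 * x3
  y["x9"]  <- if (k[["k24"]] > 0) k[["k23"]] * x3 * x5 / k[["k24"]] else 0
  y["x10"] <- if (k[["k26"]] > 0) k[["k25"]] * x1 * x5 / k[["k26"]] else 0
  if (full) {
    y["x13"] <- promoter_total / (1 + q * x1)
    y["x16"] <- q * x1 * y["x13"]
    y["x15"] <- x15_of(x1)
  } else {
    y["x13"] <- promoter_total
  }
  y
}

#' Pre-equilibrate the network without DNA damage
#'
#' Finds the steady state of the damage-free system (`k3 = k8 = k17 = 0`;
#' full model at its pre-damage basal p53 production). The pre-damage system
#' reduces structurally (all phosphorylated species vanish), so the steady
#' state is solved directly from the reduced equations and verified against
#' the full right-hand side with the criterion
#' `max|rhs| < tol * (1 + max|state|)`; if the reduction fails, long stiff
#' integration with a damped-Newton polish is used as fallback. Fails loudly
#' if no steady state is reached.
#'
#' @param params a `param_set`.
#' @param network matching network object.
#' @param feedback_off cut the transcription feedback during equilibration.
#' @param tol relative residual tolerance.
#' @param horizons increasing integration horizons for the fallback path.
#' @param must_converge if `FALSE`, return the best state with a warning
#'   instead of failing.
#' @return named steady-state vector.
#' @export
pre_equilibrate <- function(params, network, feedback_off = FALSE,
                            tol = 1e-9, horizons = c(1e4, 1e5, 1e6),
                            must_converge = TRUE) {
  k <- phase_rates(params, damage = FALSE, feedback_off = feedback_off)
  st <- pre_damage_steady(k, network, params$promoter_total)
  if (!is.null(st)) {
    r <- max(abs(network_rhs(st, k, network)))
    if (r < tol * (1 + max(abs(st)))) return(st)
  }
  y <- default_initial_state(network, params$promoter_total)
  ok <- function(x) {
    r <- max(abs(network_rhs(x, k, network)))
    r < tol * (1 + max(abs(x)))
  }
  for (h in horizons) {
    out <- integrate_network(y, k, network, times = c(0, h))
    y <- pmax(out[nrow(out), -1], 0)
    ns <- steady_state_newton(y, k, network, params$promoter_total,
                              tol = tol)
    if (ns$converged || ok(ns$state)) return(ns$state)
    if (ok(y)) return(setNames(y, paste0("x", seq_along(y))))
  }
  msg <- sprintf(paste0("pre-equilibration did not converge (residual %.3g);",
                        " the damage-free regime may be oscillatory"),
                 max(abs(network_rhs(y, k, network))))
  if (must_converge) stop(msg)
  warning(msg)
  setNames(y, paste0("x", seq_along(y)))
}

#' Simulate the DNA-damage response
#'
#' Applies the damage input (constant `k3 = k8 = k17`, and in the full model
#' the post-damage basal p53 production rate) from `t = 0` and integrates for
#' `t_end` time units. Early-response protocols start from the
#' pre-equilibrated damage-free steady state; late-response protocols start
#' from the default initial state.
#'
#' @param params a `param_set`.
#' @param protocol a [damage_protocol()].
#' @param network matching network object.
#' @param state0 optional explicit initial state (overrides the protocol's
#'   pre-equilibration choice).
#' @return a `trajectory`.
#' @export
run_damage <- function(params, protocol, network, state0 = NULL) {
  if (is.null(state0)) {
    state0 <- if (protocol$pre_equilibrate) {
      pre_equilibrate(params, network,
                      feedback_off = protocol$feedback_off)
    } else default_initial_state(network, params$promoter_total)
  }
  k <- phase_rates(params, damage = TRUE,
                   phospho_rate = protocol$phospho_rate,
                   feedback_off = protocol$feedback_off,
                   k15_factor = protocol$k15_factor)
  times <- seq(0, protocol$t_end, by = protocol$dt)
  out <- integrate_network(state0, k, network, times,
                           rtol = protocol$rtol, atol = protocol$atol)
  new_trajectory(out, network, protocol = "damage",
                 units = if (network$variant == "simple") "AU" else "minutes")
}

#' Simulate the delayed-feedback variant
#'
#' Simple-variant only: the Mdm2-production flux driven by the promoter
#' complex acts on the delayed occupancy `x14(t - tau)`. Solved with
#' [deSolve::dede()]; the history is the constant initial state. `tau = 0`
#' falls back to the plain ODE path.
#'
#' @param params a `param_set`.
#' @param protocol a [damage_protocol()].
#' @param network simple-variant network.
#' @param tau delay in model time units.
#' @param state0 optional initial state / constant history.
#' @return a `trajectory`.
#' @export
run_delay <- function(params, protocol, network, tau = 50, state0 = NULL) {
  if (network$variant != "simple")
    stop("the delayed feedback variant exists only for the simple network")
  if (tau < 0) stop("tau must be nonnegative")
  if (tau == 0) return(run_damage(params, protocol, network, state0 = state0))
  if (is.null(state0)) {
    state0 <- if (protocol$pre_equilibrate) {
      pre_equilibrate(params, network,
                      feedback_off = protocol$feedback_off)
    } else default_initial_state(network, params$promoter_total)
  }
  k <- phase_rates(params, damage = TRUE,
                   phospho_rate = protocol$phospho_rate,
                   feedback_off = protocol$feedback_off,
                   k15_factor = protocol$k15_factor)
  k33 <- k[["k33"]]
  k_no33 <- k; k_no33["k33"] <- 0
  base <- .ode_func(network)
  func <- function(t, y, parms) {
    d <- base(t, y, parms)[[1]]
    x14lag <- if (t > tau) deSolve::lagvalue(t - tau, 14) else y[14]
    d[3] <- d[3] + k33 * x14lag
    list(d)
  }
  times <- seq(0, protocol$t_end, by = protocol$dt)
  out <- deSolve::dede(y = unname(state0), times = times, func = func,
                       parms = k_no33, rtol = protocol$rtol,
                       atol = protocol$atol)
  colnames(out) <- c("time", paste0("x", seq_len(network$n_species)))
  new_trajectory(out, network, protocol = "damage_delay", units = "AU")
}

#' Simulate Nutlin treatment
#'
#' Nutlin blocks only the p53-Mdm2 interaction: the network is
#' pre-equilibrated without damage (`k11 > 0`), then simulated with
#' `k11 = 0` and all other rates at their pre-damage values. Returns the
#' total p53/Mdm2/MdmX levels divided by their pre-treatment totals.
#'
#' @param params a `param_set` (full variant).
#' @param network full-variant network.
#' @param t_end treatment duration (minutes).
#' @param dt output sampling interval.
#' @return list with the raw `trajectory` and a `folds` data frame
#'   (time, p53, Mdm2, MdmX fold-changes; all equal 1 at `t = 0`).
#' @export
run_nutlin <- function(params, network, t_end = 1440, dt = 2) {
  if (network$variant != "full")
    stop("the Nutlin protocol is defined for the full variant")
  y0 <- pre_equilibrate(params, network)
  k <- phase_rates(params, damage = FALSE)
  k["k11"] <- 0
  out <- integrate_network(y0, k, network, seq(0, t_end, by = dt))
  traj <- new_trajectory(out, network, protocol = "nutlin",
                         units = "minutes")
  pre <- vapply(c("p53", "Mdm2", "MdmX"), function(m)
    total_protein_state(y0, m, network), numeric(1))
  if (any(pre <= 0))
    stop("zero pre-treatment total protein; fold-change undefined for ",
         paste(names(pre)[pre <= 0], collapse = ", "))
  folds <- data.frame(
    time = traj$times,
    p53  = total_protein(traj, "p53")  / pre[["p53"]],
    Mdm2 = total_protein(traj, "Mdm2") / pre[["Mdm2"]],
    MdmX = total_protein(traj, "MdmX") / pre[["MdmX"]])
  list(trajectory = traj, folds = folds)
}

#' Simulate an MdmX basal-production pulse schedule
#'
#' Runs consecutive phases in which the MdmX basal production rate `k15` is
#' multiplied by a phase-specific factor, carrying the state across phase
#' boundaries (used for the pulse/memory-effect protocol: low MdmX, 100-fold
#' MdmX, back to low).
#'
#' @param params a `param_set`.
#' @param schedule list of `c(duration, k15_multiplier)` phases.
#' @param network network object.
#' @param damage apply the damage input throughout.
#' @param state0 optional initial state (default: the default initial state,
#'   as in late-response runs).
#' @param dt output sampling interval.
#' @return a `trajectory` with an extra `phase` vector marking each sample.
#' @export
run_pulse <- function(params, schedule, network, damage = TRUE,
                      state0 = NULL, dt = 1) {
  if (length(schedule) == 0) stop("empty pulse schedule")
  if (is.null(state0))
    state0 <- default_initial_state(network, params$promoter_total)
  t0 <- 0; y <- unname(state0)
  times_all <- numeric(0); states_all <- NULL; phase_all <- integer(0)
  for (p in seq_along(schedule)) {
    dur <- schedule[[p]][1]; mult <- schedule[[p]][2]
    if (dur <= 0) stop("phase durations must be positive")
    k <- phase_rates(params, damage = damage, k15_factor = mult)
    times <- seq(0, dur, by = dt)
    out <- integrate_network(y, k, network, times)
    y <- out[nrow(out), -1]
    keep <- if (p == 1) seq_len(nrow(out)) else seq(2, nrow(out))
    times_all <- c(times_all, out[keep, "time"] + t0)
    states_all <- rbind(states_all, out[keep, -1, drop = FALSE])
    phase_all <- c(phase_all, rep(p, length(keep)))
    t0 <- t0 + dur
  }
  colnames(states_all) <- paste0("x", seq_len(network$n_species))
  traj <- structure(list(times = times_all, states = states_all,
                         variant = network$variant, protocol = "pulse",
                         units = if (network$variant == "simple") "AU"
                                 else "minutes",
                         phase = phase_all),
                    class = "trajectory")
  traj
}
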