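# Conservation-reduced Jacobian: the promoter moiety (x13 + x14 [+ x16]) is
# conserved, so the full Jacobian always carries an exact zero eigenvalue.
# Substituting x13 = total - x14 - x16 and dropping the x13 row/column gives
# the Jacobian whose spectrum decides linear stability.
reduced_jacobian <- function(state, k, network) {
  J <- network_jacobian(state, k, network)
  prom <- setdiff(promoter_species(network), 13L)
  keep <- setdiff(seq_len(network$n_species), 13L)
  Jr <- J[keep, keep, drop = FALSE]
  for (p in prom) {
    pj <- match(p, keep)
    Jr[, pj] <- Jr[, pj] - J[keep, 13]
  }
  Jr
}

#' Steady state of the damage-phase network
#'
#' Damped Newton iteration on the mass-action right-hand side with the
#' free-promoter equation replaced by the conservation constraint. Intended
#' for continuation: call with the previous branch point as `guess`.
#'
#' @param k named rate vector.
#' @param network network object.
#' @param guess nonnegative starting state.
#' @param promoter_total conserved promoter total.
#' @param tol max-norm residual tolerance.
#' @return named steady state; errors on non-convergence or a negative
#'   solution.
#' @export
solve_steady_state <- function(k, network, guess, promoter_total = 1,
                               tol = 1e-11) {
  ns <- steady_state_newton(guess, k, network, promoter_total, tol = tol,
                            max_iter = 120)
  if (!ns$converged)
    stop(sprintf("steady-state Newton did not converge (residual %.3g)",
                 ns$residual))
  if (any(ns$state < -1e-9))
    stop("steady-state Newton converged to a negative state")
  ns$state
}

#' Linear stability of a steady state
#'
#' Eigenvalues of the analytic conservation-reduced Jacobian.
#'
#' @param state steady state (checked by residual).
#' @param k rate vector.
#' @param network network object.
#' @param check_residual residual bound above which the state is rejected.
#' @return list(eigenvalues, max_re, stable).
#' @export
stability <- function(state, k, network, check_residual = 1e-7) {
  r <- max(abs(network_rhs(state, k, network)))
  if (r > check_residual * (1 + max(abs(state))))
    stop(sprintf("state is not steady (residual %.3g)", r))
  ev <- eigen(reduced_jacobian(state, k, network), only.values = TRUE)$values
  mre <- max(Re(ev))
  list(eigenvalues = ev, max_re = mre, stable = mre < 0)
}

# leading real part of the reduced spectrum at the steady state continued
# from `guess`
.branch_point <- function(control, value, k, network, guess,
                          promoter_total) {
  k[control] <- value
  st <- solve_steady_state(k, network, guess, promoter_total)
  ev <- eigen(reduced_jacobian(st, k, network), only.values = TRUE)$values
  list(state = st, max_re = max(Re(ev)), eigenvalues = ev)
}

#' Trace a steady-state branch with stability and Hopf points
#'
#' Continuation along an ordered control-parameter grid, each solution
#' seeding the next Newton solve (step halving on failure, up to 8 times).
#' Hopf points are localized by bisection on the leading real part of the
#' reduced spectrum to a control-parameter tolerance of 1e-6 (relative).
#'
#' @param params a `param_set` (damage-phase rates are used; set scan axes
#'   such as `k3` explicitly first).
#' @param network network object.
#' @param control rate-constant symbol, e.g. `"k1"` or `"k15"`.
#' @param grid ordered control values; tracing starts at `grid[1]`, which
#'   should lie in a stable regime.
#' @param phospho_rate optional damage input override.
#' @return a `bifurcation_branch`: per-point steady states, leading real
#'   parts, stability flags and refined Hopf control values.
#' @export
trace_branch <- function(params, network, control, grid,
                         phospho_rate = NULL) {
  k <- phase_rates(params, damage = TRUE, phospho_rate = phospho_rate)
  P <- params$promoter_total
  k0 <- k; k0[control] <- grid[1]
  out <- integrate_network(default_initial_state(network, P), k0, network,
                           seq(0, 2e5, length.out = 201))
  guess <- pmax(out[nrow(out), -1], 0)
  # if the first grid point is already oscillatory, seed Newton from the
  # cycle average, which lies near the unstable focus
  if (is.null(tryCatch(solve_steady_state(k0, network, guess, P),
                       error = function(e) NULL)))
    guess <- pmax(colMeans(out[out[, 1] >= 1e5, -1, drop = FALSE]), 0)
  n <- length(grid)
  states <- matrix(NA_real_, n, network$n_species,
                   dimnames = list(NULL, paste0("x", seq_len(network$n_species))))
  max_re <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    prev <- if (i == 1) grid[1] else grid[i - 1]
    target <- grid[i]
    # adaptive sub-stepping between grid points
    ok <- FALSE
    for (halvings in 0:8) {
      nsub <- 2^halvings
      g <- guess; good <- TRUE
      for (s in seq_len(nsub)) {
        val <- prev + (target - prev) * s / nsub
        bp <- tryCatch(.branch_point(control, val, k, network, g, P),
                       error = function(e) NULL)
        if (is.null(bp)) { good <- FALSE; break }
        g <- bp$state
      }
      if (good) { ok <- TRUE; break }
    }
    if (!ok) stop(sprintf("branch continuation failed at %s = %g",
                          control, target))
    states[i, ] <- bp$state
    max_re[i] <- bp$max_re
    guess <- bp$state
  }
  # Hopf localization on sign changes of the leading real part
  hopf <- numeric(0)
  for (i in seq_len(n - 1)) {
    if (is.na(max_re[i]) || is.na(max_re[i + 1])) next
    if (sign(max_re[i]) * sign(max_re[i + 1]) < 0) {
      lo <- grid[i]; hi <- grid[i + 1]
      slo <- states[i, ]; flo <- max_re[i]
      while (abs(hi - lo) > 1e-6 * max(abs(lo), abs(hi), 1e-12)) {
        mid <- (lo + hi) / 2
        bp <- .branch_point(control, mid, k, network, slo, P)
        if (sign(bp$max_re) == sign(flo)) {
          lo <- mid; slo <- bp$state; flo <- bp$max_re
        } else hi <- mid
      }
      hopf <- c(hopf, (lo + hi) / 2)
    }
  }
  structure(list(control = control, grid = grid, steady_states = states,
                 max_re = max_re, stable = max_re < 0, hopf_points = hopf,
                 params = params, network = network,
                 phospho_rate = phospho_rate),
            class = "bifurcation_branch")
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat(sprintf("<bifurcation_branch> control %s over [%g, %g], %d points\n",
              x$control, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  unstable points: %d; Hopf points: %s\n",
              sum(!x$stable, na.rm = TRUE),
              if (length(x$hopf_points)) paste(signif(x$hopf_points, 6),
                                               collapse = ", ") else "none"))
  invisible(x)
}

#' Limit-cycle extrema by long integration
#'
#' Integrates from a perturbed steady state (or a supplied state), discards
#' a transient, and grows the window until the oscillation amplitude of the
#' monitored species stabilizes.
#'
#' @param params `param_set`.
#' @param network network object.
#' @param control rate symbol to override (optional).
#' @param value its value.
#' @param species monitored species name.
#' @param state0 optional initial state; default: steady-state guess plus a
#'   small perturbation, or the default initial state if no steady state is
#'   available.
#' @param t_chunk window length per amplitude estimate.
#' @param max_chunks maximum number of windows.
#' @param rel_tol relative amplitude-change convergence criterion.
#' @param phospho_rate optional damage input override.
#' @param dt output sampling interval.
#' @return list(min, max, amplitude, period, converged, final_state).
#' @export
limit_cycle <- function(params, network, control = NULL, value = NULL,
                        species = "x14", state0 = NULL, t_chunk = 20000,
                        max_chunks = 10, rel_tol = 0.02,
                        phospho_rate = NULL, dt = 1) {
  k <- phase_rates(params, damage = TRUE, phospho_rate = phospho_rate)
  if (!is.null(control)) k[control] <- value
  if (is.null(state0))
    state0 <- default_initial_state(network, params$promoter_total)
  y <- unname(state0)
  amp_prev <- NA_real_; res <- NULL
  for (ch in seq_len(max_chunks)) {
    out <- integrate_network(y, k, network, seq(0, t_chunk, by = dt))
    y <- out[nrow(out), -1]
    v <- out[out[, 1] >= t_chunk / 2, species]
    amp <- (max(v) - min(v)) / 2
    pp <- series_period(out[out[, 1] >= t_chunk / 2, "time"], v,
                        transient_frac = 0)
    res <- list(min = min(v), max = max(v), amplitude = amp,
                period = pp$period, oscillating = pp$oscillating,
                converged = FALSE, final_state = y)
    if (!is.na(amp_prev)) {
      scale <- max(amp, amp_prev, 1e-300)
      if (abs(amp - amp_prev) <= rel_tol * scale ||
          (amp < 1e-9 && amp_prev < 1e-9)) {
        res$converged <- TRUE
        return(res)
      }
    }
    amp_prev <- amp
  }
  res
}

# Generic single-shooting Newton for the periodic boundary-value problem
# phi_T(y0) = y0 with the phase anchor derivs(y0)[anchor] = 0. derivs maps a
# state to its time derivative; flow integrates it. Used both for the
# reaction networks and, in validation, for analytic test systems such as
# the Hopf normal form. n_trivial unit multipliers (flow direction plus any
# conservation laws) are discarded before the Floquet stability test.
shoot_bvp <- function(derivs, flow, y0, period, anchor = 1, tol = 1e-8,
                      max_iter = 25, n_trivial = 1, nonneg = FALSE) {
  n <- length(y0)
  resid <- function(y, T) c(flow(y, T) - y, derivs(y)[anchor])
  y <- unname(y0); T <- period
  f <- resid(y, T)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    J <- matrix(0, n + 1, n + 1)
    hy <- pmax(abs(y), 1e-7) * 1e-6
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- yp[j] + hy[j]
      J[, j] <- (resid(yp, T) - f) / hy[j]
    }
    hT <- max(abs(T), 1) * 1e-6
    J[, n + 1] <- (resid(y, T + hT) - f) / hT
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      yn <- y + lambda * step[1:n]; Tn <- T + lambda * step[n + 1]
      if ((!nonneg || all(yn > -1e-10)) && Tn > 0) {
        fn <- resid(if (nonneg) pmax(yn, 0) else yn, Tn)
        if (max(abs(fn)) < max(abs(f)) || lambda <= 1 / 64) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    if (lambda < 1e-6) break
    y <- y + lambda * step[1:n]
    if (nonneg) y <- pmax(y, 0)
    T <- T + lambda * step[n + 1]
    f <- resid(y, T)
  }
  converged <- max(abs(f)) < tol
  M <- matrix(0, n, n)
  base <- flow(y, T)
  hy <- pmax(abs(y), 1e-7) * 1e-6
  for (j in seq_len(n)) {
    yp <- y; yp[j] <- yp[j] + hy[j]
    M[, j] <- (flow(yp, T) - base) / hy[j]
  }
  mult <- eigen(M, only.values = TRUE)$values
  ord <- order(Mod(mult - 1))
  nontrivial <- if (n > n_trivial) mult[-ord[seq_len(n_trivial)]] else
    complex(0)
  list(y0 = y, period = T, residual = max(abs(f)), multipliers = mult,
       floquet_stable = all(Mod(nontrivial) < 1 + 1e-6),
       converged = converged)
}

#' Periodic orbit by single shooting
#'
#' Newton iteration on the boundary-value problem `phi_T(y0) = y0` with a
#' Poincare phase anchor (the monitored species' derivative vanishes at
#' `t = 0`). The monodromy matrix is assembled by finite differences, and
#' its multipliers (excluding the trivial flow and promoter-conservation
#' multipliers) give Floquet stability, so unstable orbits near a
#' subcritical onset are reachable by continuation from nearby solutions.
#'
#' @param params `param_set`.
#' @param network network object.
#' @param y0 initial orbit guess (a state on or near the cycle).
#' @param period period guess.
#' @param control optional rate symbol override and `value`.
#' @param value see `control`.
#' @param species phase-anchor species.
#' @param tol shooting residual tolerance.
#' @param max_iter Newton cap.
#' @param phospho_rate optional damage input override.
#' @return a `periodic_orbit`: y0, period, residual, floquet multipliers,
#'   floquet_stable, converged.
#' @export
shoot_periodic <- function(params, network, y0, period, control = NULL,
                           value = NULL, species = "x14", tol = 1e-8,
                           max_iter = 25, phospho_rate = NULL) {
  if (!is.finite(period) || period <= 0)
    stop("shoot_periodic needs a positive period guess")
  k <- phase_rates(params, damage = TRUE, phospho_rate = phospho_rate)
  if (!is.null(control)) k[control] <- value
  n <- network$n_species
  sp_i <- match(species, paste0("x", seq_len(n)))
  flow <- function(y, T)
    integrate_network(y, k, network, c(0, T),
                      rtol = 1e-10, atol = 1e-12)[2, -1]
  derivs <- function(y) network_rhs(y, k, network)
  sol <- shoot_bvp(derivs, flow, unname(y0), period, anchor = sp_i,
                   tol = tol, max_iter = max_iter, n_trivial = 2,
                   nonneg = TRUE)
  sol$y0 <- setNames(sol$y0, paste0("x", seq_len(n)))
  structure(sol, class = "periodic_orbit")
}

#' Small-amplitude periodic orbit near a Hopf point
#'
#' Shooting seeded from the linearization: `y0 = steady + delta * Re(v)`
#' with `v` the leading complex eigenvector of the reduced Jacobian and
#' period guess `2 pi / omega`. Several seed amplitudes are tried; `NULL`
#' is returned when shooting fails or collapses onto the fixed point.
#' Near a subcritical Hopf this finds the Floquet-unstable small cycle on
#' the stable side of the bifurcation.
#'
#' @param params `param_set`.
#' @param network network object.
#' @param control rate symbol to override.
#' @param value its value.
#' @param st steady-state guess near the orbit.
#' @param k damage-phase rate vector.
#' @param species phase-anchor species.
#' @param deltas relative seed amplitudes tried in turn.
#' @param tol shooting residual tolerance.
#' @return a `periodic_orbit` with an `amplitude` element, or `NULL`.
#' @export
small_hopf_orbit <- function(params, network, control, value, st, k,
                             species = "x14", deltas = c(0.05, 0.12, 0.25),
                             tol = 1e-8) {
  kk <- k; kk[control] <- value
  stn <- steady_state_newton(st, kk, network, params$promoter_total,
                             tol = 1e-12, max_iter = 120)
  st <- stn$state
  Jr <- reduced_jacobian(st, kk, network)
  ev <- eigen(Jr)
  cand <- which(abs(Im(ev$values)) > 0)
  if (length(cand) == 0) return(NULL)
  lead <- cand[which.max(Re(ev$values)[cand])]
  omega <- abs(Im(ev$values[lead]))
  if (omega <= 0) return(NULL)
  v <- ev$vectors[, lead]
  keep <- setdiff(seq_len(network$n_species), 13L)
  vfull <- numeric(network$n_species)
  vfull[keep] <- Re(v)
  prom <- setdiff(promoter_species(network), 13L)
  vfull[13] <- -sum(vfull[prom])
  vfull <- vfull / max(abs(vfull))
  scale <- max(st)
  sp_i <- match(species, paste0("x", seq_len(network$n_species)))
  for (d in deltas) {
    y0 <- pmax(st + d * scale * vfull, 0)
    po <- tryCatch(
      shoot_periodic(params, network, y0, 2 * pi / omega,
                     control = control, value = value, species = species,
                     tol = tol),
      error = function(e) NULL)
    if (is.null(po) || !po$converged) next
    if (po$period < pi / omega || po$period > 6 * pi / omega) next
    # reject collapse onto the fixed point
    amp_state <- max(abs(po$y0 - st)) / (1 + scale)
    if (amp_state < 1e-5) next
    # orbit amplitude of the monitored species
    kk2 <- kk
    out <- integrate_network(po$y0, kk2, network,
                             seq(0, po$period, length.out = 200))
    amp <- (max(out[, sp_i + 1]) - min(out[, sp_i + 1])) / 2
    if (amp < 1e-6) next
    po$amplitude <- amp
    return(po)
  }
  NULL
}

#' First Lyapunov coefficient of a Hopf point (generic core)
#'
#' Kuznetsov's projection formula for a vector field with at most quadratic
#' nonlinearity (the cubic term vanishes, as it does for any mass-action
#' network of reaction order two or less):
#' `l1 = Re(-2 <p, B(q, A^-1 B(q, conj(q)))> +
#'          <p, B(conj(q), (2 i w I - A)^-1 B(q, q))>) / (2 w)`
#' with `A` the Jacobian at the Hopf point, `q`/`p` the right/left critical
#' eigenvectors (`<p, q> = 1`) and `B` the exact bilinear form. `l1 < 0`
#' marks a supercritical, `l1 > 0` a subcritical Hopf.
#'
#' @param A Jacobian matrix at the Hopf point.
#' @param Bfun bilinear form: `Bfun(u, v)` with complex `u`, `v`.
#' @return list(l1, omega).
#' @export
lyapunov_coefficient <- function(A, Bfun) {
  n <- nrow(A)
  ev <- eigen(A)
  cpx <- which(Im(ev$values) > 0)
  if (length(cpx) == 0) stop("no complex eigenvalue pair at this point")
  lead <- cpx[which.max(Re(ev$values)[cpx])]
  omega <- Im(ev$values[lead])
  q <- ev$vectors[, lead]
  evl <- eigen(t(A))
  il <- which.min(abs(evl$values - Conj(ev$values[lead])))
  p <- evl$vectors[, il]
  p <- p / Conj(sum(Conj(p) * q))
  ip <- function(a, b) sum(Conj(a) * b)
  Bqq <- Bfun(q, q); Bqqb <- Bfun(q, Conj(q))
  t1 <- -2 * ip(p, Bfun(q, solve(A, Bqqb)))
  t2 <- ip(p, Bfun(Conj(q), solve(2i * omega * diag(n) - A, Bqq)))
  list(l1 = Re(t1 + t2) / (2 * omega), omega = omega)
}

# Exact bilinear form of the conservation-reduced network vector field.
# Mass-action fluxes are at most quadratic, so the Jacobian is affine in the
# state and B(u, v) = (J(x0 + u) - J(x0)) v exactly (no truncation error).
.network_bilinear <- function(st, k, network) {
  keep <- setdiff(seq_len(network$n_species), 13L)
  prom <- setdiff(promoter_species(network), 13L)
  A0 <- reduced_jacobian(st, k, network)
  red_to_full <- function(u) {
    uf <- numeric(network$n_species); uf[keep] <- u
    uf[13] <- -sum(uf[prom]); uf
  }
  bl_real <- function(ur, vr) {
    dJ <- reduced_jacobian(st + red_to_full(ur), k, network) - A0
    drop(dJ %*% vr)
  }
  function(u, v) {
    bl_real(Re(u), Re(v)) - bl_real(Im(u), Im(v)) +
      1i * (bl_real(Re(u), Im(v)) + bl_real(Im(u), Re(v)))
  }
}

#' Classify a Hopf bifurcation as sub- or supercritical
#'
#' Computes the first Lyapunov coefficient at the Hopf point. Because the
#' mass-action vector field is at most quadratic, the bilinear form entering
#' the normal-form projection is exact (a difference of Jacobians), so the
#' classification reduces to linear algebra at the bifurcation point --
#' robust even where near-onset transients are too slow for brute-force
#' amplitude measurement. A shooting probe for a small periodic orbit on
#' the stable side (the subcritical signature) can be added as independent
#' confirmation via [small_hopf_orbit()].
#'
#' @param branch a `bifurcation_branch` containing the Hopf point.
#' @param hopf the Hopf control value (one of `branch$hopf_points`).
#' @return list with `classification` (`"subcritical"`/`"supercritical"`),
#'   `l1` and the Hopf frequency `omega`.
#' @export
classify_hopf <- function(branch, hopf) {
  params <- branch$params; network <- branch$network
  k <- phase_rates(params, damage = TRUE,
                   phospho_rate = branch$phospho_rate)
  k[branch$control] <- hopf
  i_near <- which.min(abs(branch$grid - hopf))
  st <- steady_state_newton(branch$steady_states[i_near, ], k, network,
                            params$promoter_total, tol = 1e-13,
                            max_iter = 200)$state
  lc <- lyapunov_coefficient(reduced_jacobian(st, k, network),
                             .network_bilinear(st, k, network))
  list(classification = if (lc$l1 < 0) "supercritical" else "subcritical",
       l1 = lc$l1, omega = lc$omega, hopf = hopf)
}

#' MdmX bifurcation diagram of the full model
#'
#' Steady-state branch of the damage-phase full model as a function of the
#' MdmX basal production rate, locating the value above which oscillations
#' give way to a stable steady state.
#'
#' @param params full-variant `param_set`.
#' @param network full network.
#' @param grid ordered `k15` values (start in the stable high-MdmX regime).
#' @return a `bifurcation_branch` over `k15`.
#' @export
mdmx_bifurcation <- function(params, network,
                             grid = params$k[["k15"]] *
                               10^seq(2.5, -0.5, length.out = 25)) {
  trace_branch(params, network, control = "k15", grid = grid)
}
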