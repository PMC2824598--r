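#' Subunit-weighted total protein of one state
#'
#' @param state species concentration vector.
#' @param moiety `"p53"`, `"Mdm2"` or `"MdmX"`.
#' @param network network object (supplies subunit weights).
#' @return scalar total (dimers count twice, tetramers four times).
#' @export
total_protein_state <- function(state, moiety = c("p53", "Mdm2", "MdmX"),
                                network) {
  moiety <- match.arg(moiety)
  w <- switch(moiety, p53 = network$species$p53_subunits,
              Mdm2 = network$species$mdm2_units,
              MdmX = network$species$mdmx_units)
  sum(unname(state)[seq_len(network$n_species)] * w)
}

#' Subunit-weighted total-protein time series
#'
#' @param trajectory a `trajectory`.
#' @param moiety `"p53"`, `"Mdm2"` or `"MdmX"`.
#' @return numeric vector along the trajectory's time grid.
#' @export
total_protein <- function(trajectory, moiety = c("p53", "Mdm2", "MdmX")) {
  moiety <- match.arg(moiety)
  net <- build_network(trajectory$variant)
  w <- switch(moiety, p53 = net$species$p53_subunits,
              Mdm2 = net$species$mdm2_units,
              MdmX = net$species$mdmx_units)
  drop(trajectory$states %*% w)
}

#' Early DNA-damage response activity
#'
#' Simple variant: promoter occupancy by p53 tetramers (`x14`) read at the
#' fixed time `t = 55` AU. Full variant: maximum p53-induced mRNA (`x15`)
#' over the first 180 minutes post damage.
#'
#' @param trajectory a damage `trajectory` covering the readout window.
#' @param t_read readout time for the simple variant (AU).
#' @param window readout window for the full variant (minutes).
#' @return scalar activity.
#' @export
early_activity <- function(trajectory, t_read = 55, window = c(0, 180)) {
  if (trajectory$variant == "simple") {
    if (max(trajectory$times) < t_read)
      stop("trajectory does not cover the readout time t = ", t_read)
    approx(trajectory$times, trajectory$states[, "x14"], xout = t_read)$y
  } else {
    sel <- trajectory$times >= window[1] & trajectory$times <= window[2]
    if (!any(sel) || max(trajectory$times) < window[2])
      stop("trajectory does not cover the early-response window")
    max(trajectory$states[sel, "x15"])
  }
}

#' Switch-like effect of MdmX on the early response
#'
#' Difference in early p53 activity with versus without MdmX, both arms run
#' under the identical pre-equilibrated, feedback-off damage protocol.
#'
#' @param params `param_set` (the scan point: set `k6`, `k23`, `k25`, ...
#'   before calling).
#' @param k15_value MdmX basal production rate of the "with MdmX" arm.
#' @param network network object.
#' @param protocol damage protocol shared by both arms.
#' @return signed scalar `early_activity(with) - early_activity(without)`.
#' @export
delta_A <- function(params, k15_value, network,
                    protocol = damage_protocol(t_end = 60,
                                               feedback_off = TRUE)) {
  if (!protocol$feedback_off || !protocol$pre_equilibrate)
    stop("delta_A is defined for the pre-equilibrated feedback-off protocol")
  act <- vapply(c(0, k15_value), function(v) {
    p <- update_k(params, k15 = v)
    early_activity(run_damage(p, protocol, network))
  }, numeric(1))
  act[2] - act[1]
}

#' Oscillation-dampening effect of MdmX on the late response
#'
#' Difference of the maximal p53 activity (simple variant: `x14`) over the
#' last half of a long damage run, with versus without MdmX. Negative values
#' mean MdmX reduces the oscillation peaks.
#'
#' @param params `param_set`.
#' @param k15_value MdmX basal production rate of the "with MdmX" arm.
#' @param network network object.
#' @param t_end total simulated duration (window = its last half).
#' @param dt output sampling interval.
#' @param species monitored species column.
#' @return signed scalar `max(with) - max(without)` over the window.
#' @export
delta_M <- function(params, k15_value, network, t_end = 1e5, dt = 5,
                    species = "x14") {
  prot <- damage_protocol(pre_equilibrate = FALSE, t_end = t_end, dt = dt)
  mx <- vapply(c(0, k15_value), function(v) {
    p <- update_k(params, k15 = v)
    tr <- run_damage(p, prot, network)
    sel <- tr$times >= t_end / 2
    max(tr$states[sel, species])
  }, numeric(1))
  mx[2] - mx[1]
}

#' Detect oscillation peaks
#'
#' Local maxima above a prominence threshold (a fraction of the series range
#' after discarding an initial transient). Robust to small-amplitude ripple
#' near oscillation onset.
#'
#' @param times time grid.
#' @param values series values.
#' @param transient_frac fraction of the window discarded before analysis.
#' @param prominence_frac minimum peak height above the series minimum, as a
#'   fraction of the post-transient range.
#' @return data frame with peak `time` and `height` (possibly 0 rows).
#' @export
detect_peaks <- function(times, values, transient_frac = 0.2,
                         prominence_frac = 0.05) {
  keep <- times >= min(times) + transient_frac * diff(range(times))
  t <- times[keep]; v <- values[keep]
  if (length(v) < 3) return(data.frame(time = numeric(0), height = numeric(0)))
  rng <- diff(range(v))
  if (rng == 0) return(data.frame(time = numeric(0), height = numeric(0)))
  thr <- min(v) + prominence_frac * rng
  i <- which(diff(sign(diff(v))) == -2) + 1
  i <- i[v[i] > thr]
  data.frame(time = t[i], height = v[i])
}

#' Oscillation period from peak spacing
#'
#' Median of successive peak-to-peak intervals. With fewer than three peaks
#' the series is flagged as non-oscillating.
#'
#' @inheritParams detect_peaks
#' @return list(period, n_peaks, oscillating).
#' @export
series_period <- function(times, values, transient_frac = 0.2,
                          prominence_frac = 0.05) {
  pk <- detect_peaks(times, values, transient_frac, prominence_frac)
  if (nrow(pk) < 3)
    return(list(period = NA_real_, n_peaks = nrow(pk), oscillating = FALSE))
  list(period = median(diff(pk$time)), n_peaks = nrow(pk),
       oscillating = TRUE)
}

#' Late-response oscillation maximum
#'
#' Maximum p53-induced mRNA over the late window of a long full-model damage
#' run started from the default initial state (no pre-equilibration).
#'
#' @param params `param_set` (full variant).
#' @param network full network.
#' @param k15_factor fold applied to the MdmX basal production rate.
#' @param window late readout window in minutes.
#' @param dt output sampling interval.
#' @return scalar max `x15` over the window.
#' @export
late_max <- function(params, network, k15_factor = 1,
                     window = c(10020, 10980), dt = 1) {
  prot <- damage_protocol(pre_equilibrate = FALSE, t_end = window[2] + 20,
                          k15_factor = k15_factor, dt = dt)
  tr <- run_damage(params, prot, network)
  sel <- tr$times >= window[1] & tr$times <= window[2]
  max(tr$states[sel, "x15"])
}

#' Early-response activity scan over Mdm2 basal production
#'
#' For each `k6` on a grid and each MdmX basal-production fold, runs the
#' pre-equilibrated early damage protocol and records the maximum mRNA over
#' 0-180 min. The MdmX fold is a property of the cell, so it applies during
#' pre-equilibration too: the heterodimer reservoirs that drive the
#' switch-like response form before damage.
#'
#' @param params full-variant `param_set`.
#' @param network full network.
#' @param k6_grid Mdm2 basal production rates to scan.
#' @param k15_folds folds of the set's `k15` (0 = no MdmX).
#' @param t_end,dt early-response duration and sampling.
#' @return data frame: k6, fold, activity.
#' @export
early_response_scan <- function(params, network,
                                k6_grid, k15_folds = c(0, 1, 100),
                                t_end = 180, dt = 1) {
  res <- expand.grid(k6 = k6_grid, fold = k15_folds)
  res$activity <- NA_real_
  k15_base <- params$k[["k15"]]
  for (g in k6_grid) {
    for (f in k15_folds) {
      p <- update_k(params, k6 = g, k15 = k15_base * f)
      prot <- damage_protocol(t_end = t_end, dt = dt)
      tr <- run_damage(p, prot, network)
      res$activity[res$k6 == g & res$fold == f] <- early_activity(tr)
    }
  }
  res
}

#' Classify the MdmX effect of a parameter set
#'
#' Applies the effect-classification thresholds used in the parameter-space
#' survey: *increased dependency* when some MdmX fold raises the early
#' activity by more than 5% at low Mdm2 (k6 at or below the set's baseline)
#' and lowers it by more than 5% at high Mdm2; *dampening* when some fold
#' reduces the late-window oscillation maximum by more than 30%;
#' *no dampening* when the reduction stays below 5% for every fold.
#'
#' @param params full-variant `param_set`.
#' @param network full network.
#' @param k15_folds MdmX folds tested (relative to the set's `k15`).
#' @param k6_points number of k6 grid points per decade side.
#' @param late_window late readout window (minutes); `NULL` skips the
#'   late-response part.
#' @return an `effect_classification` list.
#' @export
classify_effect <- function(params, network,
                            k15_folds = c(0.01, 0.1, 1, 10, 100),
                            k6_points = 5, late_window = c(10020, 10980)) {
  k6_base <- params$k[["k6"]]
  grid <- 10^seq(log10(k6_base) - 2, log10(k6_base) + 2,
                 length.out = 2 * k6_points + 1)
  scan <- early_response_scan(params, network, grid,
                              k15_folds = c(0, k15_folds))
  base <- scan[scan$fold == 0, ]
  pct <- merge(scan[scan$fold != 0, ], base[, c("k6", "activity")],
               by = "k6", suffixes = c("", "_ref"))
  pct$change <- 100 * (pct$activity - pct$activity_ref) / pct$activity_ref
  low <- pct$k6 <= k6_base
  dependency_increase <- any(pct$change[low] > 5) &&
    any(pct$change[!low] < -5)

  dampening <- no_dampening <- NA
  reductions <- NULL
  if (!is.null(late_window)) {
    ref <- late_max(update_k(params, k15 = 0), network,
                    window = late_window)
    reductions <- vapply(k15_folds, function(f)
      100 * (ref - late_max(params, network, k15_factor = f,
                            window = late_window)) / ref, numeric(1))
    dampening <- any(reductions > 30)
    no_dampening <- all(reductions < 5)
  }
  structure(list(dependency_increase = dependency_increase,
                 dampening = dampening, no_dampening = no_dampening,
                 mdmx_folds_tested = k15_folds,
                 early_scan = pct, late_reductions = reductions),
            class = "effect_classification")
}

#' Heterodimer reservoir log-ratio field
#'
#' `log(x10 / x9)` — the balance between the p53:MdmX and Mdm2:MdmX
#' reservoirs — evaluated at `t = 55` AU after damage from the
#' pre-equilibrated state, over a grid of rate constants (typically `k23`
#' x `k25`, or `k6`).
#'
#' @param params simple-variant `param_set`.
#' @param network simple network.
#' @param grid data frame of rate-constant columns (named by k-symbol), one
#'   row per grid point.
#' @param t_read readout time (AU).
#' @return the grid with columns x9, x10, log_ratio (NA-flagged where a
#'   reservoir is empty).
#' @export
reservoir_log_ratio <- function(params, network, grid, t_read = 55) {
  prot <- damage_protocol(t_end = t_read, feedback_off = TRUE, dt = 1)
  out <- grid
  out$x9 <- out$x10 <- out$log_ratio <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    for (nm in names(grid)) p <- update_k(p, setNames(grid[i, nm], nm))
    tr <- run_damage(p, prot, network)
    s <- tr$states[nrow(tr$states), ]
    out$x9[i] <- s[["x9"]]; out$x10[i] <- s[["x10"]]
    if (s[["x9"]] > 0 && s[["x10"]] > 0)
      out$log_ratio[i] <- log(s[["x10"]] / s[["x9"]])
  }
  out
}
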