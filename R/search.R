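#' Cross-correlation fitness between two series
#'
#' Maximum over time lags of the normalized cross-correlation of the
#' mean-subtracted, variance-normalized series. Both series are resampled
#' onto the target's time grid before scoring.
#'
#' @param sim data frame with columns `time`, `value` (simulated series).
#' @param target data frame with columns `time`, `value`.
#' @param max_lag_frac largest lag searched, as a fraction of the series
#'   length.
#' @return list(score in `[-1, 1]`, lag in samples, flag): zero-variance
#'   input yields score 0 with `flag = "zero_variance"`.
#' @export
xcorr_fitness <- function(sim, target, max_lag_frac = 0.5) {
  g <- target$time
  a <- approx(sim$time, sim$value, xout = g, rule = 2)$y
  b <- target$value
  n <- length(g)
  if (sd(a) == 0 || sd(b) == 0)
    return(list(score = 0, lag = NA_integer_, flag = "zero_variance"))
  # population-variance standardization so a series against itself scores
  # exactly 1 at zero lag
  a <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
  b <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
  max_lag <- max(1L, floor(max_lag_frac * n))
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- seq_len(n - l) + l; ib <- seq_len(n - l)
    } else {
      ia <- seq_len(n + l); ib <- seq_len(n + l) - l
    }
    sum(a[ia] * b[ib]) / n
  }, numeric(1))
  i <- which.max(cc)
  list(score = cc[i], lag = lags[i], flag = NULL)
}

#' Oscillation fitness of a parameter set
#'
#' Simulates the damage response (full model, no pre-equilibration, as in
#' the late-response protocol), extracts the subunit-weighted total p53
#' series after a transient, and scores it against an oscillation target
#' by [xcorr_fitness()]. Also reports the oscillation floor used by the
#' stage-1 survey (maximum promoter occupancy, species `x14`).
#'
#' @param params full-variant `param_set`.
#' @param network full network.
#' @param target oscillation target (`time`, `value`).
#' @param transient discarded initial interval (minutes).
#' @return list(score, lag, max_x14, oscillating).
#' @export
oscillation_fitness <- function(params, network, target,
                                transient = 720) {
  span <- max(target$time) - min(target$time)
  dt <- median(diff(target$time))
  prot <- damage_protocol(pre_equilibrate = FALSE,
                          t_end = transient + span, dt = dt)
  tr <- tryCatch(run_damage(params, prot, network),
                 error = function(e) NULL)
  if (is.null(tr))
    return(list(score = 0, lag = NA, max_x14 = NA, oscillating = FALSE,
                flag = "simulation_failure"))
  sel <- tr$times >= transient
  sim <- data.frame(time = tr$times[sel] - transient,
                    value = total_protein(tr, "p53")[sel])
  xc <- xcorr_fitness(sim, target)
  pp <- series_period(sim$time, sim$value, transient_frac = 0)
  list(score = xc$score, lag = xc$lag,
       max_x14 = max(tr$states[sel, "x14"]),
       oscillating = pp$oscillating, flag = xc$flag)
}

#' Composite stage-2 fitness
#'
#' Combines three data fits into a scalar in `[0, 1]`: (i) the oscillation
#' cross-correlation score mapped to `(s + 1)/2`; (ii) the distance of the
#' simulated Nutlin fold-change curves to the target curves, mapped
#' `exp(-d)` with `d` the mean RMS relative deviation over the p53, Mdm2
#' and MdmX curves; (iii) the distance of the pre-damage steady-state
#' Mdm2/p53 and MdmX/Mdm2 total-protein ratios to the target ratios,
#' mapped `exp(-d)` with `d` the mean absolute log-ratio error. The three
#' sub-scores are averaged with configurable weights (default equal).
#'
#' @param params full-variant `param_set`.
#' @param network full network.
#' @param targets a [target_bundle()].
#' @param weights length-3 weights (oscillation, Nutlin, ratios).
#' @param nutlin_t_end Nutlin simulation horizon (minutes).
#' @return list(score, components); simulation failure gives score 0 with a
#'   diagnostic flag.
#' @export
composite_fitness <- function(params, network, targets,
                              weights = c(1, 1, 1) / 3,
                              nutlin_t_end = NULL) {
  osc <- oscillation_fitness(params, network, targets$oscillation)
  s_osc <- (osc$score + 1) / 2

  if (is.null(nutlin_t_end)) nutlin_t_end <- max(targets$nutlin$time)
  nl <- tryCatch(run_nutlin(params, network, t_end = nutlin_t_end,
                            dt = median(diff(targets$nutlin$time))),
                 error = function(e) NULL)
  if (is.null(nl))
    return(list(score = 0, components = NULL, flag = "nutlin_failure"))
  d_nl <- mean(vapply(c("p53", "Mdm2", "MdmX"), function(m) {
    simv <- approx(nl$folds$time, nl$folds[[m]],
                   xout = targets$nutlin$time, rule = 2)$y
    tgtv <- targets$nutlin[[m]]
    sqrt(mean(((simv - tgtv) / tgtv)^2))
  }, numeric(1)))
  s_nl <- exp(-d_nl)

  st <- tryCatch(pre_equilibrate(params, network),
                 error = function(e) NULL)
  if (is.null(st))
    return(list(score = 0, components = NULL, flag = "equilibration_failure"))
  tot <- vapply(c("p53", "Mdm2", "MdmX"), function(m)
    total_protein_state(st, m, network), numeric(1))
  r_sim <- c(mdm2_p53 = tot[["Mdm2"]] / tot[["p53"]],
             mdmx_mdm2 = tot[["MdmX"]] / tot[["Mdm2"]])
  r_tgt <- c(targets$ratios$mdm2_p53, targets$ratios$mdmx_mdm2)
  if (any(r_sim <= 0) || any(r_tgt <= 0))
    return(list(score = 0, components = NULL, flag = "zero_ratio"))
  d_r <- mean(abs(log(r_sim / r_tgt)))
  s_r <- exp(-d_r)

  comps <- c(oscillation = s_osc, nutlin = s_nl, ratios = s_r)
  list(score = sum(weights * comps) / sum(weights), components = comps,
       ratios = r_sim, flag = NULL)
}

#' Search configuration
#'
#' Free symbols follow the two-stage survey: stage 1 searches the 15
#' oscillation-relevant constants, stage 2 the 11 data-fit constants (the
#' remaining constants keep their stage-1 values; tied symbols follow
#' [apply_search_constraints()]).
#'
#' @param stage 1 or 2.
#' @param radius0 initial neighbourhood radius in log10 decades.
#' @param growth radius growth factor applied after `stagnation` candidate
#'   evaluations without improvement.
#' @param stagnation see `growth`.
#' @param max_radius radius cap (decades).
#' @param max_eval evaluation budget.
#' @param threshold stop once the best score reaches this value.
#' @param seed RNG seed (the search is deterministic given the seed).
#' @param oscillation_floor stage-1 accepted sets must reach this maximum
#'   promoter occupancy (`x14`); `NULL` disables the check.
#' @return a `search_config` list.
#' @export
search_config <- function(stage = 1, radius0 = 0.1, growth = 2,
                          stagnation = 200, max_radius = 2,
                          max_eval = 1000, threshold = NULL, seed = 1,
                          oscillation_floor = if (stage == 1) 1e-4 else NULL) {
  free <- if (stage == 1) {
    c("k2", "k3", "k10", "k11", "k12", "k13", "k27", "k28", "k29", "k30",
      "k31", "k32", "k33", "k37", "k38")
  } else {
    c("k2", "k3", "k6", "k7", "k15", "k16", "k23", "k25", "k34", "k36",
      "k38")
  }
  if (is.null(threshold)) threshold <- if (stage == 1) 0.9 else 0.25
  structure(list(stage = stage, free_symbols = free, radius0 = radius0,
                 growth = growth, stagnation = stagnation,
                 max_radius = max_radius, max_eval = max_eval,
                 threshold = threshold, seed = seed,
                 oscillation_floor = oscillation_floor),
            class = "search_config")
}

#' Radius-growing random neighbour search
#'
#' The survey algorithm: starting from a center point, candidate parameter
#' vectors are drawn uniformly in log10 space within a radius `R` of the
#' center (free symbols only; tied symbols re-derived per candidate). A
#' candidate with a higher score becomes the new center. After `stagnation`
#' evaluations without improvement, `R` grows by the configured factor up
#' to its cap. Stops at the score threshold or the evaluation budget.
#'
#' @param objective function(param_set) -> numeric score (larger is
#'   better).
#' @param center starting `param_set`.
#' @param config a [search_config()].
#' @return a `search_record`: evaluation history, best parameter set and
#'   score, seed and stage.
#' @export
neighbor_search <- function(objective, center, config) {
  set.seed(config$seed)
  free <- config$free_symbols
  centre_p <- apply_search_constraints(config$stage, center)
  centre_log <- log10(pmax(centre_p$k[free], 1e-12))
  best_score <- objective(centre_p)
  R <- config$radius0
  stagnant <- 0L
  hist <- vector("list", config$max_eval)
  for (i in seq_len(config$max_eval)) {
    u <- runif(length(free), -R, R)
    cand_log <- centre_log + u
    cand <- center
    cand$k[free] <- 10^cand_log
    cand <- apply_search_constraints(config$stage, cand)
    sc <- objective(cand)
    improved <- is.finite(sc) && sc > best_score
    if (improved) {
      best_score <- sc
      centre_log <- cand_log
      centre_p <- cand
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= config$stagnation) {
        R <- min(R * config$growth, config$max_radius)
        stagnant <- 0L
      }
    }
    hist[[i]] <- c(eval = i, score = sc, best = best_score, radius = R,
                   setNames(10^cand_log, free))
    if (best_score >= config$threshold) break
  }
  hist <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  structure(list(history = as.data.frame(hist), best_params = centre_p,
                 best_score = best_score, stage = config$stage,
                 seed = config$seed,
                 reached_threshold = best_score >= config$threshold),
            class = "search_record")
}

#' @export
print.search_record <- function(x, ...) {
  cat(sprintf("<search_record> stage %d, seed %d: %d evaluations, best score %.4f%s\n",
              x$stage, x$seed, nrow(x$history), x$best_score,
              if (x$reached_threshold) " (threshold reached)" else ""))
  invisible(x)
}

#' Project evaluated parameter sets onto principal components
#'
#' Parameters are log10-transformed and standardized before projection;
#' constant columns are dropped with a warning. Scores are binned into nine
#' equal-width levels over the observed range for color-coding.
#'
#' @param k_matrix numeric matrix: one row per evaluated set, one column
#'   per free symbol (positive values).
#' @param scores fitness score per row.
#' @return data frame with `PC1`, `PC2`, `score`, `bin` (factor, 9 levels),
#'   with the `prcomp` fit attached as attribute `"pca"`.
#' @export
pca_map <- function(k_matrix, scores) {
  if (nrow(k_matrix) < 3) stop("need at least 3 parameter sets")
  lx <- log10(pmax(as.matrix(k_matrix), 1e-300))
  keep <- apply(lx, 2, function(cc) sd(cc) > 0)
  if (!all(keep)) {
    warning("dropping constant parameter column(s): ",
            paste(colnames(lx)[!keep], collapse = ", "))
    lx <- lx[, keep, drop = FALSE]
  }
  if (ncol(lx) < 2) {
    # degenerate input (e.g. identical sets): every point sits at the origin
    out <- data.frame(PC1 = rep(0, nrow(lx)), PC2 = rep(0, nrow(lx)),
                      score = scores, bin = factor(rep(1, nrow(lx))))
    return(out)
  }
  pc <- prcomp(lx, center = TRUE, scale. = TRUE)
  rng <- range(scores)
  brk <- if (diff(rng) > 0) seq(rng[1], rng[2], length.out = 10) else
    rng[1] + seq(-1, 1, length.out = 10)
  bin <- cut(scores, breaks = brk, include.lowest = TRUE)
  out <- data.frame(PC1 = pc$x[, 1], PC2 = pc$x[, 2], score = scores,
                    bin = bin)
  attr(out, "pca") <- pc
  out
}
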