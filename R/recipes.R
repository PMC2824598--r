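# Named reproduction recipes tying the modules together. Each recipe
# recomputes one of the study's figure- or table-level analyses (at problem
# sizes documented in the methods vignette) and returns its result tables;
# with an output directory, tables are written as TSV together with a run
# manifest (seed, package version, solver tolerances) sufficient to re-run
# the recipe identically. The numbered scripts under analysis/ are thin
# drivers over these recipes.

.recipe_names <- c("fig3", "fig4", "fig5", "fig6", "fig7", "fig9",
                   "fig10", "fig11", "table2_classify", "s3", "s4",
                   "s5_nutlin", "s7_sensitivity")

#' Run a named reproduction recipe
#'
#' @param name one of `fig3`, `fig4`, `fig5`, `fig6`, `fig7`, `fig9`,
#'   `fig10`, `fig11`, `table2_classify`, `s3`, `s4`, `s5_nutlin`,
#'   `s7_sensitivity`.
#' @param out_dir optional output directory for TSV tables and the run
#'   manifest.
#' @param seed RNG seed recorded in the manifest (the recipes are
#'   deterministic; the seed matters only for stochastic add-ons).
#' @return named list of data frames (recipe-dependent).
#' @export
run_recipe <- function(name, out_dir = NULL, seed = 1) {
  if (!name %in% .recipe_names)
    stop("unknown recipe '", name, "'; available: ",
         paste(.recipe_names, collapse = ", "))
  set.seed(seed)
  res <- switch(
    name,
    fig3 = recipe_fig3(), fig4 = recipe_fig4(), fig5 = recipe_fig5(),
    fig6 = recipe_fig6(), fig7 = recipe_fig7(), fig9 = recipe_fig9(),
    fig10 = recipe_fig10(), fig11 = recipe_fig11(),
    table2_classify = recipe_table2(), s3 = recipe_s3(), s4 = recipe_s4(),
    s5_nutlin = recipe_s5(), s7_sensitivity = recipe_s7())
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res)) {
      write.table(res[[nm]], file.path(out_dir, paste0(name, "_", nm,
                                                       ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest <- data.frame(
      key = c("recipe", "seed", "package_version", "ode_rtol", "ode_atol",
              "R_version"),
      value = c(name, seed,
                as.character(utils::packageVersion("p53mdmx")),
                "1e-8", "1e-10", paste(R.version$major, R.version$minor,
                                       sep = ".")))
    write.table(manifest, file.path(out_dir, paste0(name, "_manifest.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(res)
}

# Early damage-response time series at contrasting Mdm2/MdmX production
# rates (simple model, feedback off, pre-equilibrated).
recipe_fig3 <- function() {
  net <- build_network("simple")
  p <- load_parameter_set("col4")
  combos <- expand.grid(k6 = c(1e-3, 0.05, 0.5), k15 = c(0, 0.05, 5))
  prot <- damage_protocol(phospho_rate = 0.1, t_end = 55,
                          feedback_off = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    pp <- update_k(p, k6 = combos$k6[i], k15 = combos$k15[i])
    tr <- run_damage(pp, prot, net)
    data.frame(k6 = combos$k6[i], k15 = combos$k15[i], time = tr$times,
               x14 = tr$states[, "x14"])
  }))
  list(timeseries = out)
}

# p53 activity at t = 55 AU versus damage strength and versus Mdm2
# production, for three MdmX production rates.
recipe_fig4 <- function() {
  net <- build_network("simple")
  p <- load_parameter_set("col4")
  k15s <- c(0, 0.05, 5)
  phospho <- 10^seq(-3, 0, length.out = 9)
  vs_damage <- do.call(rbind, lapply(k15s, function(k15)
    do.call(rbind, lapply(phospho, function(ph) {
      pp <- update_k(p, k15 = k15, k6 = 0.05)
      tr <- run_damage(pp, damage_protocol(phospho_rate = ph, t_end = 55,
                                           feedback_off = TRUE), net)
      data.frame(k15 = k15, phospho = ph, k6 = 0.05,
                 activity = early_activity(tr))
    }))))
  k6s <- 10^seq(-3, 0.7, length.out = 9)
  vs_mdm2 <- do.call(rbind, lapply(k15s, function(k15)
    do.call(rbind, lapply(k6s, function(g) {
      pp <- update_k(p, k15 = k15, k6 = g)
      tr <- run_damage(pp, damage_protocol(phospho_rate = 0.1, t_end = 55,
                                           feedback_off = TRUE), net)
      data.frame(k15 = k15, phospho = 0.1, k6 = g,
                 activity = early_activity(tr))
    }))))
  list(vs_damage = vs_damage, vs_mdm2 = vs_mdm2)
}

# Switch-like effect of MdmX (delta A) at the two marked operating points
# and over a small binding-constant grid.
recipe_fig5 <- function() {
  net <- build_network("simple")
  p <- update_k(load_parameter_set("col4"), k3 = 0.1, k8 = 0.1,
                k17 = 0.1)
  pts <- do.call(rbind, lapply(c(0.001, 1), function(g) {
    dA <- delta_A(update_k(p, k6 = g), k15_value = 5, net)
    data.frame(k6 = g, k15 = 5, delta_A = dA)
  }))
  grid <- expand.grid(k25 = 10^seq(-2, 1, length.out = 4),
                      k23 = 10^seq(-2, 1, length.out = 4))
  field <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    pp <- update_k(p, k6 = 0.05, k23 = grid$k23[i], k25 = grid$k25[i])
    data.frame(k23 = grid$k23[i], k25 = grid$k25[i],
               delta_A = delta_A(pp, k15_value = 5, net))
  }))
  list(marked_points = pts, field = field)
}

# Late-response dampening measure (delta M) on a small k1 x k3 grid.
recipe_fig6 <- function() {
  net <- build_network("simple")
  p <- load_parameter_set("col5")
  grid <- expand.grid(k1 = c(0.05, 0.2, 0.8), k3 = c(0.003, 0.0086851,
                                                     0.03))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    pp <- update_k(p, k1 = grid$k1[i], k3 = grid$k3[i])
    dM <- delta_M(pp, k15_value = 10, net, t_end = 5e4, dt = 10)
    data.frame(k1 = grid$k1[i], k3 = grid$k3[i], delta_M = dM)
  }))
  list(delta_M = out)
}

# Bifurcation diagram of the oscillatory simple model: branch, Hopf points
# and criticality for three MdmX production rates.
recipe_fig7 <- function() {
  net <- build_network("simple")
  p5 <- update_k(load_parameter_set("col5"), k3 = 0.0086851)
  grid <- 10^seq(log10(0.005), log10(2.4), length.out = 26)
  rows <- list(); branches <- list()
  for (k15 in c(0, 0.2, 0.6)) {
    p <- update_k(p5, k15 = k15)
    br <- trace_branch(p, net, "k1", grid)
    branches[[as.character(k15)]] <-
      data.frame(k15 = k15, k1 = br$grid, x14 = br$steady_states[, "x14"],
                 max_re = br$max_re, stable = br$stable)
    for (h in sort(br$hopf_points)) {
      cl <- classify_hopf(br, h)
      rows[[length(rows) + 1]] <-
        data.frame(k15 = k15, hopf_k1 = h, l1 = cl$l1,
                   omega = cl$omega, classification = cl$classification)
    }
  }
  list(branch = do.call(rbind, branches), hopf = do.call(rbind, rows))
}

# Early-response activity versus Mdm2 production for the fitted full-model
# sets at MdmX folds 0..100.
recipe_fig9 <- function() {
  net <- build_network("full")
  folds <- c(0, 0.01, 0.1, 1, 10, 100)
  out <- do.call(rbind, lapply(c("col8", "col9"), function(lab) {
    p <- load_parameter_set(lab)
    k6b <- p$k[["k6"]]
    grid <- 10^seq(log10(k6b) - 2, log10(k6b) + 2, length.out = 9)
    sc <- early_response_scan(p, net, grid, k15_folds = folds)
    sc$set <- lab
    sc
  }))
  list(early_scan = out)
}

# Late response of the fitted OSC1P1-derived set: dampening time series,
# MdmX pulse (memory effect) and the k15 bifurcation branch.
recipe_fig10 <- function() {
  net <- build_network("full")
  p <- load_parameter_set("col8")
  series <- do.call(rbind, lapply(c(1, 100), function(f) {
    tr <- run_damage(p, damage_protocol(pre_equilibrate = FALSE,
                                        t_end = 6000, k15_factor = f,
                                        dt = 2), net)
    data.frame(fold = f, time = tr$times, x15 = tr$states[, "x15"])
  }))
  pulse <- run_pulse(p, list(c(2000, 1), c(2000, 100), c(2000, 1)), net,
                     dt = 2)
  pulse_df <- data.frame(time = pulse$times, phase = pulse$phase,
                         x15 = pulse$states[, "x15"])
  br <- mdmx_bifurcation(p, net)
  branch <- data.frame(k15 = br$grid, x15 = br$steady_states[, "x15"],
                       max_re = br$max_re, stable = br$stable)
  list(dampening = series, pulse = pulse_df, k15_branch = branch)
}

# Heterodimer reservoir balance log(x10/x9) at t = 55 AU for low and high
# Mdm2 production.
recipe_fig11 <- function() {
  net <- build_network("simple")
  p <- update_k(load_parameter_set("col4"), k3 = 0.1, k8 = 0.1, k17 = 0.1,
                k15 = 0.05)
  grid <- expand.grid(k25 = 10^seq(-2, 1, length.out = 4),
                      k23 = 10^seq(-2, 1, length.out = 4))
  out <- do.call(rbind, lapply(c(0.001, 1), function(g) {
    f <- reservoir_log_ratio(update_k(p, k6 = g), net, grid)
    f$k6 <- g
    f
  }))
  list(reservoir = out)
}

# Effect classification of the two fitted sets (dependency increase,
# dampening / no dampening).
recipe_table2 <- function() {
  net <- build_network("full")
  out <- do.call(rbind, lapply(c("col8", "col9"), function(lab) {
    cl <- classify_effect(load_parameter_set(lab), net, k6_points = 3)
    data.frame(set = lab, dependency_increase = cl$dependency_increase,
               dampening = cl$dampening, no_dampening = cl$no_dampening,
               max_late_reduction = max(cl$late_reductions))
  }))
  list(classification = out)
}

# Heterodimer-knockout control: late-window maximum versus MdmX production
# with and without heterodimer formation.
recipe_s3 <- function() {
  net <- build_network("simple")
  p <- load_parameter_set("col7")
  k15s <- c(0.0001, 0.01, 0.1, 1, 10)
  out <- do.call(rbind, lapply(c(TRUE, FALSE), function(with_het) {
    pp <- if (with_het) p else update_k(p, k23 = 0, k25 = 0)
    do.call(rbind, lapply(k15s, function(v) {
      tr <- run_damage(update_k(pp, k15 = v),
                       damage_protocol(pre_equilibrate = FALSE,
                                       t_end = 2e5, dt = 20), net)
      sel <- tr$times >= 1e5
      data.frame(heterodimers = with_het, k15 = v,
                 late_max = max(tr$states[sel, "x14"]))
    }))
  }))
  list(late_max = out)
}

# Delayed-feedback oscillations with and without MdmX.
recipe_s4 <- function() {
  net <- build_network("simple", delay_on = TRUE)
  p <- load_parameter_set("col6")
  out <- do.call(rbind, lapply(c(0, 0.1), function(v) {
    tr <- run_delay(update_k(p, k15 = v),
                    damage_protocol(pre_equilibrate = FALSE, t_end = 3000),
                    net, tau = 50)
    data.frame(k15 = v, time = tr$times, x14 = tr$states[, "x14"])
  }))
  list(timeseries = out)
}

# Nutlin fold-change curves for both fitted sets.
recipe_s5 <- function() {
  net <- build_network("full")
  out <- do.call(rbind, lapply(c("col8", "col9"), function(lab) {
    nl <- run_nutlin(load_parameter_set(lab), net, t_end = 1440, dt = 5)
    cbind(set = lab, nl$folds)
  }))
  list(folds = out)
}

# Local sensitivity ranking for both fitted sets.
recipe_s7 <- function() {
  out <- do.call(rbind, lapply(c("col8", "col9"), function(lab) {
    st <- local_sensitivity(load_parameter_set(lab),
                            build_network("full"))
    cbind(set = lab, as.data.frame(st))
  }))
  list(sensitivity = out)
}
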