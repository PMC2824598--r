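# Published kinetic-constant sets. Columns col4-col7 parameterize the simple
# network variant, col8/col9 the full variant (fitted sets derived from the
# OSC1P1 and OSC2P1 oscillatory regions of parameter space). Cells printed as
# a scan range rather than a single value are stored as NA here; their
# documented defaults and scan axes live in .scan_axes / .scan_defaults.
# k33 holds the row-33 rate for simple-variant sets and the row-34 (mRNA
# production) rate for full-variant sets; k34-k36 are the p53:promoter
# binding/basal-transcription constants, k37/k38 the mRNA degradation and
# mRNA-driven Mdm2 production constants (full variant only).
.param_columns <- local({
  m <- rbind(
    #        col4      col5      col6     col7      col8       col9
    k1  = c(5.000e-2,       NA, 1.000e-1, 5.000e-1,       NA,       NA),
    k2  = c(2.100e-2, 8.000e-4, 4.400e-3, 8.000e-4, 3.923e-3, 3.710e-3),
    k3  = c(      NA,       NA, 1.000e+0, 1.000e-1, 1.578e-2, 1.048e+1),
    k4  = c(2.000e-2, 2.365e-2, 2.500e-1, 2.365e-2, 3.156e-4, 2.095e-1),
    k5  = c(1.700e-3, 2.000e-3, 4.400e-3, 2.000e-3, 1.224e-2, 1.542e-3),
    k6  = c(      NA, 1.500e-3, 3.000e-3, 1.500e-3, 7.994e-5, 6.528e-4),
    k7  = c(5.000e-3, 5.000e-4, 2.190e-2, 5.000e-4, 7.592e-5, 1.275e-2),
    k8  = c(      NA, 2.000e-1, 1.000e+0, 2.000e-1, 1.578e-2, 1.048e+1),
    k9  = c(2.000e-2, 2.000e-2, 2.500e-1, 2.000e-2, 3.156e-4, 2.095e-1),
    k10 = c(2.198e+1, 5.000e-5, 8.000e+0, 5.000e-5, 1.826e-1, 2.436e-2),
    k11 = c(1.000e-1, 1.000e+0, 1.000e+0, 5.000e-1, 3.056e+1, 2.760e+0),
    k12 = c(5.000e-2, 1.750e-2, 1.000e-1, 1.750e-2, 1.608e-1, 4.284e-1),
    k13 = c(5.000e+0, 2.500e+0, 5.000e+0, 1.000e+0, 7.917e-1, 9.259e+0),
    k14 = c(0.000e+0, 1.000e-1, 0.000e+0, 1.000e-1, 1.583e-1, 1.852e+0),
    k15 = c(      NA, 0.000e+0, 1.000e+0,       NA, 2.173e-5, 8.436e-5),
    k16 = c(5.000e-3, 3.425e-2, 6.850e-2, 3.425e-2, 3.155e-4, 1.373e-4),
    k17 = c(      NA, 2.000e-2, 1.000e+0, 2.000e-2, 1.578e-2, 1.048e+1),
    k18 = c(2.000e-2, 2.000e-2, 2.500e-1, 2.000e-2, 3.156e-4, 2.095e-1),
    k19 = c(5.000e-3, 3.425e-2, 6.850e-2, 3.425e-2, 1.224e-3, 1.542e-4),
    k20 = c(1.100e+1, 4.150e-3, 2.000e+0, 4.150e-3, 3.056e+1, 2.760e+0),
    k21 = c(3.640e-5, 8.000e-4, 2.000e-3, 8.000e-4, 1.608e-1, 4.284e-1),
    k22 = c(7.319e+0, 4.825e-2, 2.000e+0, 4.825e-2, 7.917e-1, 9.259e+0),
    k23 = c(1.000e-1, 2.500e-1, 9.372e-1, 1.211e-1, 3.427e+2, 7.356e+0),
    k24 = c(5.000e-2, 3.500e-1, 2.130e-2, 1.830e-2, 1.608e-1, 4.284e-1),
    k25 = c(1.000e-1, 1.211e-1, 3.925e-1, 1.211e-1, 2.596e-1, 1.022e+1),
    k26 = c(5.000e-2, 1.830e-2, 5.000e-2, 1.830e-2, 1.608e-1, 4.284e-1),
    k27 = c(8.090e-1, 5.000e-4, 1.000e+0, 5.000e-4, 4.206e-1, 2.535e-3),
    k28 = c(6.110e-2, 5.000e-4, 5.000e-1, 5.000e-4, 7.918e-1, 5.194e-2),
    k29 = c(8.090e-1, 2.500e-5, 1.000e+0, 2.500e-5, 1.543e+0, 5.275e-2),
    k30 = c(6.110e-2, 5.000e-4, 5.000e-1, 5.000e-4, 1.016e-1, 3.103e-1),
    k31 = c(8.090e-1, 2.500e-5, 1.000e+0, 2.500e-5, 4.715e-1, 1.626e+0),
    k32 = c(6.110e-2, 5.000e-4, 5.000e-1, 5.000e-4, 2.555e-1, 3.059e-1),
    k33 = c(0.000e+0, 1.000e-1, 4.000e+1, 5.000e-1, 7.170e-1, 1.801e+0),
    k34 = c(0, 0, 0, 0, 6.293e-3, 4.015e-2),
    k35 = c(0, 0, 0, 0, 2.794e+0, 1.117e+2),
    k36 = c(0, 0, 0, 0, 6.545e-2, 9.043e-2),
    k37 = c(0, 0, 0, 0, 5.551e-2, 3.813e-2),
    k38 = c(0, 0, 0, 0, 3.708e+0, 1.456e+2)
  )
  colnames(m) <- paste0("col", 4:9)
  m
})

.param_variant <- c(col4 = "simple", col5 = "simple", col6 = "simple",
                    col7 = "simple", col8 = "full", col9 = "full")

# Scan axes for cells printed as ranges, and the documented default used
# when no scan value is set explicitly (log-midpoint of the range, or the
# middle entry of a printed value list).
.scan_axes <- list(
  col4 = list(k3  = c(1e-3, 1), k8 = c(1e-3, 1), k17 = c(1e-3, 1),
              k6  = c(1e-3, 10^0.7),
              k15 = c(0, 0.05, 5)),
  col5 = list(k1  = c(0.028118, 10),
              k3  = c(1e-5, 10)),
  col7 = list(k15 = c(0.0001, 0.001, 0.005, 0.01, 0.02, 0.05, 0.075,
                      0.1, 0.5, 1, 2, 8, 10, 12, 20),
              k23 = c(1e-5, 20), k25 = c(1e-5, 20))
)

.scan_defaults <- list(
  col4 = c(k3 = 10^-1.5, k8 = 10^-1.5, k17 = 10^-1.5,
           k6 = 10^-1.15, k15 = 0.05),
  col5 = c(k1 = sqrt(0.028118 * 10), k3 = 1e-2),
  col7 = c(k15 = 0.1, k23 = 0.1211, k25 = 0.1211)
)

#' Load a published kinetic-constant set
#'
#' Returns the rate constants of one of the six parameter columns: `col4`
#' (initial simple-model set), `col5` (oscillatory simple-model set used for
#' the bifurcation study), `col6` (delayed-feedback oscillatory set), `col7`
#' (heterodimer-knockout study set), `col8` and `col9` (fitted full-model
#' sets derived from the OSC1P1 and OSC2P1 search regions). Cells printed as
#' scan ranges are populated with a documented default (log-midpoint of the
#' range, or the middle of a printed value list) and recorded as scan axes;
#' analysis routines that scan them always set them explicitly.
#'
#' The full-model sets carry two basal p53 production rates: 0.003 before
#' DNA damage and 0.01 after (p53 translation increases after damage).
#'
#' @param label one of `"col4"` .. `"col9"`.
#' @return A `param_set` object: named rates `k1`..`k38`, pre-/post-damage
#'   basal p53 production, the network variant, the total promoter
#'   concentration (default 1 concentration unit) and scan-axis metadata.
#' @export
load_parameter_set <- function(label) {
  if (!label %in% colnames(.param_columns))
    stop("unknown parameter-set label: ", label,
         " (available: ", paste(colnames(.param_columns), collapse = ", "), ")")
  k <- .param_columns[, label]
  scan <- .scan_axes[[label]]
  if (!is.null(scan)) {
    def <- .scan_defaults[[label]]
    k[names(def)] <- def
  }
  variant <- .param_variant[[label]]
  if (variant == "full") {
    k1_pre <- 0.003; k1_post <- 0.01
    k["k1"] <- k1_post
  } else {
    k1_pre <- k1_post <- k[["k1"]]
  }
  structure(list(
    k = k, k1_predamage = k1_pre, k1_postdamage = k1_post,
    promoter_total = 1, label = label, variant = variant,
    delay = if (label == "col6") 50 else 0,
    scan = scan
  ), class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %s (%s variant)%s\n", x$label, x$variant,
              if (x$delay > 0) sprintf(", delay %g", x$delay) else ""))
  cat(sprintf("  k1 pre/post damage: %g / %g; promoter total %g\n",
              x$k1_predamage, x$k1_postdamage, x$promoter_total))
  if (length(x$scan))
    cat("  scan axes:", paste(names(x$scan), collapse = ", "), "\n")
  invisible(x)
}

#' Modify rate constants of a parameter set
#'
#' @param params a `param_set`.
#' @param ... named rate constants to override, e.g. `k6 = 1e-4`. `k1` sets
#'   both the pre- and post-damage basal p53 production rate.
#' @return the modified `param_set`.
#' @export
update_k <- function(params, ...) {
  upd <- c(...)
  if (length(upd) == 0) return(params)
  bad <- setdiff(names(upd), .k_symbols)
  if (length(bad)) stop("unknown rate symbols: ", paste(bad, collapse = ", "))
  params$k[names(upd)] <- upd
  if ("k1" %in% names(upd)) {
    params$k1_predamage <- params$k1_postdamage <- upd[["k1"]]
  }
  params
}

#' Tie rate constants the way the two-stage parameter survey does
#'
#' Stage 1 (oscillation search over 15 free constants) ties
#' `k7 = k5 = k2`, `k14 = 0.2 k13`, `k8 = k3` and `k9 = k4 = 0.02 k3`.
#' Stage 2 (data-fitting search over the 11 listed free constants) ties
#' `k10 = k17 = k3` and `k4 = k9 = k18 = 0.02 k3`.
#'
#' @param stage 1 or 2.
#' @param base a `param_set` whose free symbols are already set.
#' @return the `param_set` with tied symbols overwritten.
#' @export
apply_search_constraints <- function(stage, base) {
  k <- base$k
  if (stage == 1) {
    k["k7"] <- k["k5"] <- k["k2"]
    k["k14"] <- 0.2 * k["k13"]
    k["k8"] <- k["k3"]
    k["k9"] <- k["k4"] <- 0.02 * k["k3"]
  } else if (stage == 2) {
    k["k10"] <- k["k17"] <- k["k3"]
    k["k4"] <- k["k9"] <- k["k18"] <- 0.02 * k["k3"]
  } else stop("stage must be 1 or 2")
  base$k <- k
  base
}

#' Rate vector for one protocol phase
#'
#' `damage` toggles the phosphorylation input (`k3 = k8 = k17`, set to
#' `phospho_rate` when given, otherwise the set's own values) and, in the
#' full variant, switches `k1` between its pre- and post-damage values.
#' `feedback_off` zeroes `k33` and `k14` (early-response studies with the
#' transcription feedback cut).
#'
#' @param params a `param_set`.
#' @param damage damage phase (`TRUE`) or damage-free phase (`FALSE`).
#' @param phospho_rate optional common phosphorylation rate.
#' @param feedback_off cut the transcription feedback.
#' @param k15_factor fold applied to the MdmX basal production rate.
#' @return named rate vector `k1`..`k38`.
#' @export
phase_rates <- function(params, damage = TRUE, phospho_rate = NULL,
                        feedback_off = FALSE, k15_factor = 1) {
  k <- params$k
  if (damage) {
    k["k1"] <- params$k1_postdamage
    if (!is.null(phospho_rate))
      k["k3"] <- k["k8"] <- k["k17"] <- phospho_rate
  } else {
    k["k1"] <- params$k1_predamage
    k["k3"] <- k["k8"] <- k["k17"] <- 0
  }
  if (feedback_off) k["k33"] <- k["k14"] <- 0
  k["k15"] <- k["k15"] * k15_factor
  k
}
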