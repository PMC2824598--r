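# Synthetic stand-ins for the external calibration data used by the
# fitness functions: a pulsatile p53 oscillation pattern with ~6 h
# peak-to-peak spacing, monotone saturating Nutlin fold-change curves, and
# scalar total-protein ratios. These emulate the shape and scale of the
# published observations so that fitness scoring and parameter search are
# testable offline; they are not digitized from any figure.

#' Synthetic p53 oscillation target
#'
#' A train of raised-cosine pulses on a baseline (pulsatile rather than
#' sinusoidal, resembling observed p53 dynamics), with optional amplitude
#' damping and additive Gaussian noise. Deterministic given the seed.
#'
#' @param period peak-to-peak interval (minutes; default 360 = 6 h).
#' @param n_peaks number of pulses (>= 2).
#' @param peak_width pulse width as a fraction of the period.
#' @param baseline constant offset.
#' @param amplitude pulse height.
#' @param damping per-period multiplicative amplitude decay (0 = none).
#' @param noise_sd additive noise standard deviation.
#' @param dt sampling interval (minutes).
#' @param seed RNG seed for the noise.
#' @return data frame `time`, `value` (nonnegative).
#' @export
make_oscillation_target <- function(period = 360, n_peaks = 6,
                                    peak_width = 0.45, baseline = 0.1,
                                    amplitude = 1, damping = 0,
                                    noise_sd = 0, dt = 5, seed = 1) {
  if (period <= 0) stop("period must be positive")
  if (n_peaks < 2) stop("need at least 2 peaks")
  t <- seq(0, n_peaks * period, by = dt)
  v <- rep(baseline, length(t))
  w <- peak_width * period
  for (i in seq_len(n_peaks)) {
    tc <- (i - 0.5) * period
    idx <- abs(t - tc) < w / 2
    a <- amplitude * (1 - damping)^(i - 1)
    v[idx] <- v[idx] + a * 0.5 * (1 + cos(2 * pi * (t[idx] - tc) / w))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(v), 0, noise_sd)
  }
  data.frame(time = t, value = pmax(v, 0))
}

#' Synthetic Nutlin fold-change target curves
#'
#' Monotone saturating fold-change curves
#' `1 + (plateau - 1) * (1 - exp(-rate * t))` for total p53, Mdm2 and MdmX
#' after blocking the p53-Mdm2 interaction. All curves start at exactly 1.
#'
#' @param plateaus named plateau fold-changes for `p53`, `Mdm2`, `MdmX`
#'   (each >= 1).
#' @param rate saturation rate (per minute; > 0).
#' @param grid time grid (minutes).
#' @return data frame `time`, `p53`, `Mdm2`, `MdmX`.
#' @export
make_nutlin_target <- function(plateaus = c(p53 = 3, Mdm2 = 5, MdmX = 1.5),
                               rate = 0.005,
                               grid = seq(0, 1440, by = 10)) {
  if (rate < 0) stop("rate must be nonnegative")
  if (any(plateaus < 1)) stop("plateaus must be >= 1")
  f <- function(p) 1 + (p - 1) * (1 - exp(-rate * grid))
  data.frame(time = grid, p53 = f(plateaus[["p53"]]),
             Mdm2 = f(plateaus[["Mdm2"]]), MdmX = f(plateaus[["MdmX"]]))
}

#' Synthetic total-protein ratio targets
#'
#' @param mdm2_p53 target total Mdm2 / total p53 ratio.
#' @param mdmx_mdm2 target total MdmX / total Mdm2 ratio.
#' @return list of the two scalars.
#' @export
make_ratio_target <- function(mdm2_p53 = 2, mdmx_mdm2 = 1) {
  if (mdm2_p53 <= 0 || mdmx_mdm2 <= 0) stop("ratios must be positive")
  list(mdm2_p53 = mdm2_p53, mdmx_mdm2 = mdmx_mdm2)
}

#' Bundle of synthetic calibration targets
#'
#' @param seed RNG seed propagated to the oscillation target.
#' @param period oscillation period (minutes).
#' @param noise_sd oscillation noise level.
#' @param ... further arguments to [make_oscillation_target()].
#' @return a `target_bundle` list: `oscillation`, `nutlin`, `ratios`,
#'   `seed`. Identical seeds give identical bundles.
#' @export
target_bundle <- function(seed = 1, period = 360, noise_sd = 0, ...) {
  structure(list(
    oscillation = make_oscillation_target(period = period,
                                          noise_sd = noise_sd,
                                          seed = seed, ...),
    nutlin = make_nutlin_target(),
    ratios = make_ratio_target(),
    seed = seed
  ), class = "target_bundle")
}

#' Write / read a target bundle as delimited text
#'
#' The bundle is stored as `oscillation.tsv`, `nutlin.tsv` and a
#' `manifest.tsv` holding the ratio targets and the seed.
#'
#' @param bundle a [target_bundle()].
#' @param dir directory (created if needed).
#' @return `write_target_bundle`: the directory, invisibly;
#'   `read_target_bundle`: the bundle.
#' @export
write_target_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(bundle$oscillation, file.path(dir, "oscillation.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(bundle$nutlin, file.path(dir, "nutlin.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- data.frame(key = c("mdm2_p53", "mdmx_mdm2", "seed"),
                         value = c(bundle$ratios$mdm2_p53,
                                   bundle$ratios$mdmx_mdm2, bundle$seed))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_target_bundle
#' @export
read_target_bundle <- function(dir) {
  man <- read.delim(file.path(dir, "manifest.tsv"))
  val <- setNames(man$value, man$key)
  structure(list(
    oscillation = read.delim(file.path(dir, "oscillation.tsv")),
    nutlin = read.delim(file.path(dir, "nutlin.tsv")),
    ratios = list(mdm2_p53 = unname(val["mdm2_p53"]),
                  mdmx_mdm2 = unname(val["mdmx_mdm2"])),
    seed = unname(val["seed"])
  ), class = "target_bundle")
}
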