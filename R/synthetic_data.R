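# Seeded generators for every input the pipeline consumes, built around
# immutable per-variant presets. The presets bundle the published melting
# temperatures (DSF and equilibrium) with capture rate constants
# calibrated so that the published 60-min partitioning endpoints at 3 uM
# chaperonin emerge from the defaults (~25% soluble for I154F, ~55% for
# D122Y, and essentially no loss for wild type).

# run expr with a fixed RNG stream, restoring the caller's stream after
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.PRESETS <- list(
  WT = list(
    name = "WT",
    capture = list(k_u = 1e-4, k_f = 1.0, k_c = 0.3, k_agg = 0),
    tm_dsf = 55.1, tm_equilibrium = 66.3, dh_vh = 45),
  D122Y = list(
    name = "D122Y",
    capture = list(k_u = 0.015, k_f = 0.450, k_c = 0.30, k_agg = 0.005),
    tm_dsf = 48.8, tm_equilibrium = 50.4, dh_vh = 45),
  I154F = list(
    name = "I154F",
    capture = list(k_u = 0.030, k_f = 0.300, k_c = 0.35, k_agg = 0.02),
    tm_dsf = 39.1, tm_equilibrium = 50.7, dh_vh = 45)
)

#' Frataxin variant presets
#'
#' Immutable parameter sets for wild-type frataxin and the two
#' Friedreich's ataxia clinical variants. `tm_dsf` and `tm_equilibrium`
#' are the published melting temperatures (differential scanning
#' fluorimetry and equilibrium denaturation respectively); the capture
#' rate constants are package calibrations chosen so the default
#' simulations reproduce the published 60-minute partitioning endpoints;
#' `dh_vh = 45` kcal/mol is a package default giving a realistic ~10 degC
#' transition width (no enthalpies were published).
#'
#' @param name One of "WT", "D122Y", "I154F".
#' @return A list of class `variant_preset` with elements `name`,
#'   `capture` (a [capture_params()]), `tm_dsf`, `tm_equilibrium`,
#'   `dh_vh`.
#' @examples
#' preset("I154F")$capture$k_u  # 0.03 min^-1
#' @export
preset <- function(name) {
  if (!name %in% names(.PRESETS)) {
    stop("unknown preset '", name, "'; choose one of ",
         paste(names(.PRESETS), collapse = ", "), call. = FALSE)
  }
  p <- .PRESETS[[name]]
  p$capture <- do.call(capture_params, p$capture)
  class(p) <- "variant_preset"
  p
}

#' @rdname preset
#' @export
preset_names <- function() names(.PRESETS)

#' Generate a replicate-averaged soluble-fraction time course
#'
#' Integrates the capture scheme for the preset's rate constants, then
#' adds i.i.d. Gaussian noise per replicate and per time point and
#' returns the per-point replicate mean and standard deviation, mimicking
#' the triplicate spectroscopic sampling of a bead partitioning assay.
#'
#' @param preset A [preset()].
#' @param cond An [experiment_condition()].
#' @param times Sampling times (minutes), starting at 0.
#' @param noise_sd Gaussian noise SD on the soluble fraction (default
#'   0.02).
#' @param n_replicates Replicates per time point (default 3).
#' @param seed RNG seed; required for reproducibility.
#' @return A [time_course()] with `sd` column and the condition attached.
#' @export
gen_timecourse <- function(preset, cond,
                           times = c(0, 1, 2, 5, 10, 15, 20, 30, 45, 60),
                           noise_sd = 0.02, n_replicates = 3, seed = 1) {
  stopifnot(inherits(preset, "variant_preset"),
            inherits(cond, "experiment_condition"), noise_sd >= 0)
  traj <- simulate_capture(preset$capture, cond, times)
  clean <- traj$soluble_frac
  if (noise_sd == 0) {
    return(time_course(times, clean, sd = rep(0, length(times)),
                       condition = cond))
  }
  reps <- .with_seed(seed, matrix(
    clean + stats::rnorm(length(clean) * n_replicates, sd = noise_sd),
    nrow = length(clean)))
  m <- rowMeans(reps)
  # keep within the container's physical bounds; noise excursions beyond
  # [0, 1.1] would be rejected on loading real data too
  m <- pmin(pmax(m, 0), 1.1)
  time_course(times, m, sd = apply(reps, 1, stats::sd), condition = cond)
}

#' Generate a DSF-style melt curve
#'
#' Evaluates the two-state observation model over a temperature grid with
#' linear fluorescence baselines and adds Gaussian noise scaled to the
#' transition amplitude (the unfolded-minus-folded baseline separation at
#' the midpoint).
#'
#' @param preset A [preset()]; `tm_dsf` (or `tm_equilibrium` when
#'   `equilibrium = TRUE`) and `dh_vh` set the transition.
#' @param t_range Length-2 scan range in Celsius.
#' @param step Grid step in Celsius (default 0.5).
#' @param noise_frac Noise SD as a fraction of the transition amplitude.
#' @param seed RNG seed.
#' @param baselines Named list with `a_n`, `b_n`, `a_u`, `b_u`.
#' @param equilibrium If `TRUE`, generate a normalized fraction-unfolded
#'   curve (baselines 0 and 1, flat) from `tm_equilibrium` instead of a
#'   fluorescence trace from `tm_dsf`.
#' @return A [melt_curve()].
#' @export
gen_meltcurve <- function(preset, t_range = c(25, 80), step = 0.5,
                          noise_frac = 0.01, seed = 1,
                          baselines = list(a_n = 1000, b_n = 1,
                                           a_u = 9000, b_u = -4),
                          equilibrium = FALSE) {
  stopifnot(inherits(preset, "variant_preset"), step > 0)
  if (diff(t_range) <= 0) stop("degenerate temperature range", call. = FALSE)
  temps <- seq(t_range[1], t_range[2], by = step)
  if (equilibrium) {
    fit <- two_state_fit(preset$tm_equilibrium, preset$dh_vh,
                         a_n = 0, b_n = 0, a_u = 1, b_u = 0)
    amplitude <- 1
  } else {
    fit <- two_state_fit(preset$tm_dsf, preset$dh_vh,
                         a_n = baselines$a_n, b_n = baselines$b_n,
                         a_u = baselines$a_u, b_u = baselines$b_u)
    amplitude <- abs((fit$a_u + fit$b_u * fit$tm) -
                       (fit$a_n + fit$b_n * fit$tm))
  }
  sig <- melt_signal(temps, fit)
  if (noise_frac > 0) {
    sig <- sig + .with_seed(seed, stats::rnorm(length(temps),
                                               sd = noise_frac * amplitude))
  }
  melt_curve(temps, sig, probe = if (equilibrium) "fraction_unfolded"
             else "SYPRO Orange")
}

#' Generate a UV-visible spectrum
#'
#' A Gaussian aromatic band centred at 280 nm (SD 15 nm) plus a Rayleigh
#' lambda^-4 scattering baseline scaled so that A(350) equals
#' `scatter_a350`, plus Gaussian instrument noise, on a 240-400 nm, 1 nm
#' grid.
#'
#' @param conc_au Peak height of the 280 nm band (AU).
#' @param scatter_a350 Scatter amplitude expressed as its 350 nm value.
#' @param noise_sd Instrument noise SD in AU (default 0.001).
#' @param seed RNG seed.
#' @param label Spectrum label.
#' @return A [uv_spectrum()].
#' @export
gen_spectrum <- function(conc_au, scatter_a350 = 0, noise_sd = 0.001,
                         seed = 1, label = "") {
  stopifnot(conc_au >= 0, scatter_a350 >= 0, noise_sd >= 0)
  wl <- 240:400
  band <- conc_au * exp(-(wl - 280)^2 / (2 * 15^2))
  scatter <- scatter_a350 * (350 / wl)^4
  ab <- band + scatter
  if (noise_sd > 0) {
    ab <- ab + .with_seed(seed, stats::rnorm(length(wl), sd = noise_sd))
  }
  uv_spectrum(wl, ab, label = label)
}

#' Generate replicate densitometry records
#'
#' Soluble/pellet band pairs for one condition with multiplicative
#' Gaussian noise of coefficient of variation `cv` on each band; the
#' expected fraction soluble equals `true_fraction`.
#'
#' @param true_fraction True soluble fraction in (0, 1).
#' @param n_replicates Number of replicates (default 3).
#' @param cv Coefficient of variation of each band (default 0.1).
#' @param seed RNG seed.
#' @param variant,condition Labels copied into the records.
#' @return Data frame with columns `variant`, `condition`, `replicate`,
#'   `s_band`, `p_band`.
#' @export
gen_densitometry <- function(true_fraction, n_replicates = 3, cv = 0.1,
                             seed = 1, variant = "", condition = "") {
  if (true_fraction <= 0 || true_fraction >= 1) {
    stop("true_fraction must lie in (0, 1)", call. = FALSE)
  }
  total <- 100
  noise <- .with_seed(seed, matrix(
    stats::rnorm(2 * n_replicates, mean = 1, sd = cv), ncol = 2))
  s <- pmax(total * true_fraction * noise[, 1], 0)
  p <- pmax(total * (1 - true_fraction) * noise[, 2], 0)
  data.frame(variant = variant, condition = condition,
             replicate = seq_len(n_replicates), s_band = s, p_band = p)
}
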