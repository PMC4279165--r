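# Two-state van 't Hoff analysis of thermal unfolding curves, for both
# DSF fluorescence traces (free linear baselines) and equilibrium
# denaturation curves already normalized to fraction unfolded (baselines
# fixed at 0 and 1). DeltaCp is taken as zero: the model has two
# thermodynamic parameters, Tm and the van 't Hoff enthalpy.

# Gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.987e-3

#' Fraction unfolded under the two-state van 't Hoff model
#'
#' \deqn{K(T) = \exp\left[\frac{\Delta H_{vH}}{R}\left(\frac{1}{T_m} -
#'   \frac{1}{T}\right)\right], \qquad f_u = \frac{K}{1 + K}}
#' with absolute temperatures (K = degC + 273.15) and
#' R = 1.987e-3 kcal mol^-1 K^-1. At `t = tm` the equilibrium constant is
#' 1 and exactly half the molecules are unfolded.
#'
#' @param t Temperature(s) in Celsius.
#' @param tm Melting temperature in Celsius.
#' @param dh_vh Van 't Hoff enthalpy (kcal/mol), must be positive for a
#'   cooperative transition.
#' @return Fraction unfolded in (0, 1).
#' @examples
#' fraction_unfolded(55.1, 55.1, 45)  # 0.5
#' @export
fraction_unfolded <- function(t, tm, dh_vh) {
  if (!is.finite(dh_vh) || dh_vh <= 0) {
    stop("dh_vh must be positive for a cooperative transition",
         call. = FALSE)
  }
  tk <- t + 273.15
  tmk <- tm + 273.15
  keq <- exp((dh_vh / .R_KCAL) * (1 / tmk - 1 / tk))
  keq / (1 + keq)
}

#' Two-state melt-curve parameter set
#'
#' Container for the six parameters of the linear-baseline observation
#' model: signal(T) = (a_n + b_n T)(1 - f_u) + (a_u + b_u T) f_u.
#'
#' @param tm Melting temperature (Celsius).
#' @param dh_vh Van 't Hoff enthalpy (kcal/mol).
#' @param a_n,b_n Folded (native) baseline intercept and slope.
#' @param a_u,b_u Unfolded baseline intercept and slope.
#' @param tm_se,rss,converged Fit diagnostics (optional).
#' @return An object of class `two_state_fit`.
#' @export
two_state_fit <- function(tm, dh_vh, a_n = 0, b_n = 0, a_u = 1, b_u = 0,
                          tm_se = NA_real_, rss = NA_real_,
                          converged = TRUE) {
  structure(list(tm = tm, dh_vh = dh_vh, a_n = a_n, b_n = b_n,
                 a_u = a_u, b_u = b_u, tm_se = tm_se, rss = rss,
                 converged = converged, edge_transition = FALSE),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state fit: Tm = %.2f degC (dH_vH = %.1f kcal/mol)%s\n",
              x$tm, x$dh_vh,
              if (isTRUE(x$edge_transition)) " [transition at scan edge]"
              else ""))
  invisible(x)
}

#' Predicted melt signal for a two-state parameter set
#'
#' @param t Temperature(s) in Celsius.
#' @param fit A [two_state_fit()].
#' @return Predicted signal(s).
#' @export
melt_signal <- function(t, fit) {
  stopifnot(inherits(fit, "two_state_fit"))
  fu <- fraction_unfolded(t, fit$tm, fit$dh_vh)
  (fit$a_n + fit$b_n * t) * (1 - fu) + (fit$a_u + fit$b_u * t) * fu
}

#' Thermal melt curve
#'
#' @param temps Temperatures (Celsius), strictly increasing; a fittable
#'   curve needs at least 20 points spanning at least 20 degC.
#' @param signal Fluorescence (or normalized fraction-unfolded) values.
#' @param heating_rate Scan rate in degC/min (metadata).
#' @param probe Probe label (metadata), e.g. "SYPRO Orange".
#' @return A data frame of class `melt_curve`.
#' @export
melt_curve <- function(temps, signal, heating_rate = 1.5, probe = "") {
  if (length(temps) != length(signal)) {
    stop("temps and signal must have equal length", call. = FALSE)
  }
  if (any(diff(temps) <= 0)) {
    stop("temperatures must be strictly increasing (no repeats)",
         call. = FALSE)
  }
  out <- data.frame(temp_c = temps, signal = signal)
  attr(out, "heating_rate") <- heating_rate
  attr(out, "probe") <- probe
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Fit the two-state model to a melt curve
#'
#' Estimates Tm, the van 't Hoff enthalpy and (unless fixed) the two
#' linear baselines by Levenberg-Marquardt least squares. Tm is started
#' at the temperature of the maximum smoothed first derivative of the
#' signal; baselines are started from linear fits to the first and last
#' 15% of points. With `fix_baselines = c(0, 1)` the machinery fits
#' already-normalized equilibrium denaturation curves (fraction unfolded
#' vs temperature) with only Tm and dH_vH free.
#'
#' Curves with no usable transition (flat, or monotone with no
#' inflection inside the scan) raise a no-transition error; a transition
#' within 2 degC of either scan edge is flagged, not rejected. DSF traces
#' often decay after the unfolded-state maximum (dye release from
#' aggregates); `truncate_post_max = TRUE` drops points beyond the signal
#' maximum before fitting.
#'
#' @param curve A [melt_curve()].
#' @param fix_baselines `NULL` (free linear baselines) or a length-2
#'   numeric giving fixed constant folded/unfolded baselines.
#' @param truncate_post_max Drop points after the global signal maximum.
#' @return A [two_state_fit()] with `tm_se`, `rss` and `converged` set.
#' @export
fit_melt <- function(curve, fix_baselines = NULL,
                     truncate_post_max = FALSE) {
  stopifnot(inherits(curve, "melt_curve"))
  df <- as.data.frame(curve)
  if (truncate_post_max) {
    df <- df[seq_len(which.max(df$signal)), , drop = FALSE]
  }
  if (nrow(df) < 20 || diff(range(df$temp_c)) < 20) {
    stop("need >= 20 points spanning >= 20 degC", call. = FALSE)
  }
  sig_range <- diff(range(df$signal))
  if (sig_range < .Machine$double.eps^0.5 ||
      sig_range < 1e-3 * max(abs(df$signal), 1e-12)) {
    stop("no transition detected: signal is flat", call. = FALSE)
  }
  # Tm start: max of smoothed derivative
  dsig <- diff(df$signal) / diff(df$temp_c)
  if (length(dsig) >= 5) {
    dsig <- stats::filter(dsig, rep(1 / 5, 5), sides = 2)
  }
  tmid <- (df$temp_c[-1] + df$temp_c[-nrow(df)]) / 2
  ok <- is.finite(dsig)
  tm0 <- tmid[ok][which.max(abs(dsig[ok]))]
  n <- nrow(df)
  edge_n <- max(3L, ceiling(0.15 * n))
  lo <- df[seq_len(edge_n), ]
  hi <- df[seq(n - edge_n + 1, n), ]
  fixed <- !is.null(fix_baselines)
  if (fixed) {
    stopifnot(length(fix_baselines) == 2)
    form <- stats::as.formula(sprintf(
      "signal ~ %.17g + (%.17g - %.17g) * fraction_unfolded(temp_c, tm, dh)",
      fix_baselines[1], fix_baselines[2], fix_baselines[1]))
    mk <- function(dh0) list(tm = tm0, dh = dh0)
    lower <- c(tm = min(df$temp_c) - 10, dh = 1)
    upper <- c(tm = max(df$temp_c) + 10, dh = 1000)
  } else {
    cf_n <- stats::coef(stats::lm(signal ~ temp_c, data = lo))
    cf_u <- stats::coef(stats::lm(signal ~ temp_c, data = hi))
    form <- signal ~ (a_n + b_n * temp_c) *
      (1 - fraction_unfolded(temp_c, tm, dh)) +
      (a_u + b_u * temp_c) * fraction_unfolded(temp_c, tm, dh)
    mk <- function(dh0) list(tm = tm0, dh = dh0,
                             a_n = unname(cf_n[1]), b_n = unname(cf_n[2]),
                             a_u = unname(cf_u[1]), b_u = unname(cf_u[2]))
    lower <- c(tm = min(df$temp_c) - 10, dh = 1,
               a_n = -Inf, b_n = -Inf, a_u = -Inf, b_u = -Inf)
    upper <- c(tm = max(df$temp_c) + 10, dh = 1000,
               a_n = Inf, b_n = Inf, a_u = Inf, b_u = Inf)
  }
  fit <- NULL
  for (dh0 in c(50, 20, 100, 200)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = mk(dh0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out <- two_state_fit(NA_real_, NA_real_, converged = FALSE)
    return(out)
  }
  cf <- stats::coef(fit)
  if (cf[["tm"]] < min(df$temp_c) || cf[["tm"]] > max(df$temp_c)) {
    stop("no transition detected inside the scanned range", call. = FALSE)
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  out <- two_state_fit(
    tm = unname(cf[["tm"]]), dh_vh = unname(cf[["dh"]]),
    a_n = if (fixed) fix_baselines[1] else unname(cf[["a_n"]]),
    b_n = if (fixed) 0 else unname(cf[["b_n"]]),
    a_u = if (fixed) fix_baselines[2] else unname(cf[["a_u"]]),
    b_u = if (fixed) 0 else unname(cf[["b_u"]]),
    tm_se = if (is.null(se)) NA_real_ else unname(se[["tm"]]),
    rss = sum(stats::residuals(fit)^2), converged = TRUE)
  if (cf[["tm"]] < min(df$temp_c) + 2 || cf[["tm"]] > max(df$temp_c) - 2) {
    out$edge_transition <- TRUE
    warning("transition lies within 2 degC of the scan edge",
            call. = FALSE)
  }
  out
}

#' Melting-temperature shift relative to a control
#'
#' @param fit,control Converged [two_state_fit()] objects; `control` is
#'   typically the no-osmolyte condition.
#' @return `fit$tm - control$tm` in Celsius (positive = stabilizing).
#' @export
delta_tm <- function(fit, control) {
  stopifnot(inherits(fit, "two_state_fit"),
            inherits(control, "two_state_fit"))
  if (!isTRUE(fit$converged) || !isTRUE(control$converged)) {
    stop("delta_tm requires converged fits", call. = FALSE)
  }
  fit$tm - control$tm
}

#' Osmolyte concentration series of melting temperatures
#'
#' @param osmolyte Osmolyte name (e.g. "TMAO", "trehalose").
#' @param concs Molar concentrations, non-negative and increasing.
#' @param tms Melting temperatures (Celsius), one per concentration.
#' @param control_tm Melting temperature of the no-osmolyte control.
#' @return An object of class `osmolyte_series`; `dtms` is computed as
#'   `tms - control_tm`.
#' @export
osmolyte_series <- function(osmolyte, concs, tms, control_tm) {
  if (length(concs) != length(tms)) {
    stop("concs and tms must have equal length", call. = FALSE)
  }
  if (any(concs < 0) || any(diff(concs) <= 0)) {
    stop("concs must be non-negative and increasing", call. = FALSE)
  }
  structure(list(osmolyte = osmolyte, concs = concs, tms = tms,
                 control_tm = control_tm, dtms = tms - control_tm),
            class = "osmolyte_series")
}

#' Concentration dependence of osmolyte stabilization
#'
#' Ordinary least-squares slope of Tm against osmolyte concentration,
#' with a sign classification: slopes more than two standard errors from
#' zero are "stabilizing" (positive) or "destabilizing" (negative),
#' otherwise "neutral".
#'
#' @param series An [osmolyte_series()] with at least 3 concentrations.
#' @return A list with `slope` (degC per molar), `slope_se`, and `sign`.
#' @export
stabilization_trend <- function(series) {
  stopifnot(inherits(series, "osmolyte_series"))
  if (length(series$concs) < 3) {
    stop("at least 3 concentrations required", call. = FALSE)
  }
  fit <- stats::lm(tms ~ concs,
                   data = data.frame(concs = series$concs,
                                     tms = series$tms))
  cf <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  slope <- cf["concs", "Estimate"]
  se <- cf["concs", "Std. Error"]
  sign <- if (!is.finite(se) || se == 0) {
    if (slope > 0) "stabilizing" else if (slope < 0) "destabilizing"
    else "neutral"
  } else if (slope > 2 * se) "stabilizing"
  else if (slope < -2 * se) "destabilizing"
  else "neutral"
  list(slope = unname(slope), slope_se = unname(se), sign = sign)
}
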