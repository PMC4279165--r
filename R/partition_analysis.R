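# Pseudo-first-order analysis of soluble-fraction time courses and
# hyperbolic saturation of the apparent partitioning rate with chaperonin
# concentration. Fits use Levenberg-Marquardt least squares with
# data-driven starts and a multi-start fallback.

#' Soluble-fraction time course for one assay condition
#'
#' @param times Sampling times (minutes), strictly increasing, first >= 0.
#' @param soluble_frac Fraction of the starting soluble protein at each
#'   time. Values slightly above 1 (up to 1.1) are tolerated as noise.
#' @param sd Optional per-point standard deviation across replicates;
#'   used as inverse-variance weights when fitting.
#' @param condition Optional [experiment_condition()] metadata.
#' @return A data frame of class `time_course`.
#' @export
time_course <- function(times, soluble_frac, sd = NULL, condition = NULL) {
  if (length(times) != length(soluble_frac)) {
    stop("times and soluble_frac must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0) || times[1] < 0) {
    stop("times must be strictly increasing and start at >= 0",
         call. = FALSE)
  }
  if (any(soluble_frac < 0 | soluble_frac > 1.1)) {
    stop("soluble_frac must lie in [0, 1.1]", call. = FALSE)
  }
  if (!is.null(sd) && (length(sd) != length(times) || any(sd < 0))) {
    stop("sd must be non-negative and match times in length", call. = FALSE)
  }
  out <- data.frame(time_min = times, soluble_frac = soluble_frac)
  if (!is.null(sd)) out$sd <- sd
  attr(out, "condition") <- condition
  class(out) <- c("time_course", "data.frame")
  out
}

# Shared LM fit with multi-start over k; returns NULL if every start fails.
.fit_decay_lm <- function(df, starts, lower, upper, weights, fixed_sinf) {
  form <- if (fixed_sinf) {
    soluble_frac ~ s0 * exp(-k_app * time_min)
  } else {
    soluble_frac ~ s_inf + (s0 - s_inf) * exp(-k_app * time_min)
  }
  for (st in starts) {
    args <- list(form, data = df, start = st, lower = lower, upper = upper,
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

#' Fit a pseudo-first-order decay to a soluble-fraction time course
#'
#' Fits \eqn{S(t) = S_\infty + (S_0 - S_\infty) e^{-k_{app} t}} by
#' weighted least squares (weights `1/sd^2` when per-point standard
#' deviations are present). The initial rate guess is `ln(2)/t_half`,
#' with `t_half` the first crossing of the midpoint between the series
#' extremes; on failure three log-spaced rate starts are tried. A flat
#' series is reported as `k_app = 0` with the `degenerate_flat` flag
#' rather than an error.
#'
#' @param tc A [time_course()].
#' @param fix_plateau_zero If `TRUE`, constrain the plateau
#'   \eqn{S_\infty = 0} (simple exponential decay to zero).
#' @return An object of class `decay_fit` with elements `k_app`, `s0`,
#'   `s_inf`, `k_app_se`, `rss`, `converged`, `degenerate_flat`.
#' @examples
#' t <- c(0, 1, 5, 10, 20, 30, 45, 60)
#' tc <- time_course(t, 0.1 + 0.9 * exp(-0.02 * t))
#' fit_first_order(tc)$k_app  # 0.02
#' @export
fit_first_order <- function(tc, fix_plateau_zero = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  if (nrow(tc) < 4) {
    stop("at least 4 time points are required", call. = FALSE)
  }
  s <- tc$soluble_frac
  if (diff(range(s)) < .Machine$double.eps^0.5) {
    return(structure(list(k_app = 0, s0 = s[1],
                          s_inf = if (fix_plateau_zero) 0 else s[1],
                          k_app_se = NA_real_, rss = 0, converged = TRUE,
                          degenerate_flat = TRUE),
                     class = "decay_fit"))
  }
  w <- if (!is.null(tc$sd) && all(tc$sd > 0)) 1 / tc$sd^2 else NULL
  mid <- (max(s) + min(s)) / 2
  below <- which(s <= mid)
  t_half <- if (length(below)) max(tc$time_min[below[1]], tc$time_min[2]) else
    max(tc$time_min) / 2
  k0 <- log(2) / t_half
  mk_start <- function(k) {
    if (fix_plateau_zero) list(s0 = s[1], k_app = k)
    else list(s0 = s[1], s_inf = s[length(s)], k_app = k)
  }
  starts <- lapply(c(k0, k0 / 10, k0 * 10, k0 / 100), mk_start)
  if (fix_plateau_zero) {
    lower <- c(s0 = 0, k_app = 0); upper <- c(s0 = 2, k_app = Inf)
  } else {
    lower <- c(s0 = 0, s_inf = 0, k_app = 0)
    upper <- c(s0 = 2, s_inf = 2, k_app = Inf)
  }
  fit <- .fit_decay_lm(tc, starts, lower, upper, w, fix_plateau_zero)
  if (is.null(fit)) {
    return(structure(list(k_app = NA_real_, s0 = NA_real_, s_inf = NA_real_,
                          k_app_se = NA_real_, rss = NA_real_,
                          converged = FALSE, degenerate_flat = FALSE),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(k_app = unname(cf[["k_app"]]),
                 s0 = unname(cf[["s0"]]),
                 s_inf = if (fix_plateau_zero) 0 else unname(cf[["s_inf"]]),
                 k_app_se = if (is.null(se)) NA_real_ else
                   unname(se[["k_app"]]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = TRUE, degenerate_flat = FALSE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Pseudo-first-order decay: k_app = %.4g min^-1 (s0 = %.3g, s_inf = %.3g)%s\n",
    x$k_app, x$s0, x$s_inf,
    if (isTRUE(x$degenerate_flat)) " [flat series]" else ""))
  invisible(x)
}

#' Evaluate a fitted decay at time t
#'
#' @param fit A `decay_fit`.
#' @param t Time(s) in minutes, non-negative.
#' @return Predicted soluble fraction(s).
#' @export
fraction_remaining <- function(fit, t) {
  stopifnot(inherits(fit, "decay_fit"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  fit$s_inf + (fit$s0 - fit$s_inf) * exp(-fit$k_app * t)
}

#' Apparent-rate profile across chaperonin concentrations
#'
#' @param el_concs Chaperonin oligomer concentrations (uM), non-negative.
#' @param k_apps Apparent partitioning rates (min^-1), one per
#'   concentration.
#' @param k_app_errs Optional standard errors on the rates (used as
#'   inverse-variance weights in [fit_rate_saturation()]).
#' @return A data frame of class `rate_profile`.
#' @export
rate_profile <- function(el_concs, k_apps, k_app_errs = NULL) {
  if (length(el_concs) != length(k_apps)) {
    stop("el_concs and k_apps must have equal length", call. = FALSE)
  }
  if (any(el_concs < 0)) stop("el_concs must be non-negative", call. = FALSE)
  out <- data.frame(el_uM = el_concs, k_app_per_min = k_apps)
  if (!is.null(k_app_errs)) out$k_app_err <- k_app_errs
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Fit the hyperbolic saturation of apparent rate vs chaperonin
#'
#' Fits \eqn{k_{app}([EL]) = k_{max} [EL] / (k_{half} + [EL])}. Under the
#' capture scheme the limiting rate `k_max` estimates the unfolding rate
#' `k_u` (unfolding becomes rate limiting at saturating chaperonin) and
#' `k_half` estimates `k_f / k_c`. If the fitted `k_half` exceeds ten
#' times the largest tested concentration the profile is flagged as
#' `saturation_not_reached`.
#'
#' @param profile A [rate_profile()] with at least 3 distinct positive
#'   concentrations.
#' @return An object of class `saturation_fit` with `k_max`, `k_half`,
#'   standard errors, `rss`, `converged`, `saturation_not_reached`.
#' @export
fit_rate_saturation <- function(profile) {
  stopifnot(inherits(profile, "rate_profile"))
  pos <- profile[profile$el_uM > 0, , drop = FALSE]
  if (length(unique(pos$el_uM)) < 3) {
    stop("at least 3 distinct positive chaperonin concentrations required",
         call. = FALSE)
  }
  if (all(pos$k_app_per_min == 0)) {
    stop("degenerate profile: all apparent rates are zero", call. = FALSE)
  }
  w <- if (!is.null(pos$k_app_err) && all(pos$k_app_err > 0))
    1 / pos$k_app_err^2 else NULL
  kmax0 <- max(pos$k_app_per_min)
  half_idx <- which(pos$k_app_per_min >= kmax0 / 2)[1]
  khalf0 <- max(pos$el_uM[half_idx], min(pos$el_uM) / 2)
  fit <- NULL
  for (kh in c(khalf0, khalf0 / 5, khalf0 * 5)) {
    args <- list(k_app_per_min ~ k_max * el_uM / (k_half + el_uM),
                 data = pos, start = list(k_max = kmax0, k_half = kh),
                 lower = c(k_max = 0, k_half = 1e-9),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(k_max = NA_real_, k_half = NA_real_,
                          k_max_se = NA_real_, k_half_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          saturation_not_reached = NA),
                     class = "saturation_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(k_max = unname(cf[["k_max"]]),
                 k_half = unname(cf[["k_half"]]),
                 k_max_se = if (is.null(se)) NA_real_ else
                   unname(se[["k_max"]]),
                 k_half_se = if (is.null(se)) NA_real_ else
                   unname(se[["k_half"]]),
                 rss = sum(stats::residuals(fit)^2),
                 converged = TRUE,
                 saturation_not_reached =
                   unname(cf[["k_half"]]) > 10 * max(pos$el_uM)),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "Rate saturation: k_max = %.4g min^-1, k_half = %.4g uM%s\n",
    x$k_max, x$k_half,
    if (isTRUE(x$saturation_not_reached)) " [saturation not reached]" else ""))
  invisible(x)
}

#' Fit decays for several concentrations and assemble a rate profile
#'
#' Convenience wrapper: fits [fit_first_order()] to each time course and
#' collects the apparent rates (with standard errors, used downstream as
#' weights) into a [rate_profile()].
#'
#' @param tcs A list of [time_course()] objects whose `condition`
#'   attributes carry the chaperonin concentration.
#' @param fix_plateau_zero Passed to [fit_first_order()].
#' @return A [rate_profile()].
#' @export
profile_from_timecourses <- function(tcs, fix_plateau_zero = FALSE) {
  fits <- lapply(tcs, fit_first_order, fix_plateau_zero = fix_plateau_zero)
  el <- vapply(tcs, function(tc) attr(tc, "condition")$el_conc, numeric(1))
  rate_profile(el,
               vapply(fits, `[[`, numeric(1), "k_app"),
               vapply(fits, `[[`, numeric(1), "k_app_se"))
}
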