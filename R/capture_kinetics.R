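# Forward kinetic model of chaperonin capture:
#   N <-> I (k_u / k_f), I + EL -> C (k_c, irreversible), 2 I -> A (k_agg)
# Units are minutes and micromolar throughout; temperature and urea are
# metadata only (they act through the rate constants).

#' Microscopic rate constants of the capture scheme
#'
#' Bundles the four mass-action rate constants of the folding/capture/
#' aggregation scheme: reversible exchange between the native state N and a
#' chaperonin-binding intermediate I, irreversible capture of I by
#' chaperonin, and a competing second-order aggregation channel.
#'
#' @param k_u Unfolding rate N -> I (min^-1).
#' @param k_f Refolding rate I -> N (min^-1).
#' @param k_c Capture association rate of I with chaperonin
#'   (uM^-1 min^-1). Site multiplicity of the oligomer is absorbed here;
#'   chaperonin concentrations are oligomer concentrations.
#' @param k_agg Aggregation rate, second order in I (uM^-1 min^-1).
#' @return An object of class `capture_params`.
#' @examples
#' capture_params(k_u = 0.03, k_f = 0.3, k_c = 0.35, k_agg = 0.02)
#' @export
capture_params <- function(k_u, k_f, k_c, k_agg = 0) {
  rates <- c(k_u = k_u, k_f = k_f, k_c = k_c, k_agg = k_agg)
  if (any(!is.finite(rates))) {
    stop("all rate constants must be finite", call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("rate constants must be non-negative", call. = FALSE)
  }
  structure(as.list(rates), class = "capture_params")
}

#' @export
print.capture_params <- function(x, ...) {
  cat("Capture-scheme rate constants:\n")
  cat(sprintf("  k_u   = %g min^-1 (unfolding)\n", x$k_u))
  cat(sprintf("  k_f   = %g min^-1 (refolding)\n", x$k_f))
  cat(sprintf("  k_c   = %g uM^-1 min^-1 (capture)\n", x$k_c))
  cat(sprintf("  k_agg = %g uM^-1 min^-1 (aggregation)\n", x$k_agg))
  invisible(x)
}

#' Experimental condition for a partitioning assay
#'
#' @param el_conc Chaperonin oligomer concentration (uM, on beads).
#' @param protein0 Starting protein concentration (uM).
#' @param temperature_c Assay temperature in Celsius (metadata).
#' @param urea_m Molar urea (metadata).
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(el_conc, protein0 = 2,
                                 temperature_c = 45, urea_m = 1) {
  if (!is.finite(el_conc) || el_conc < 0) {
    stop("el_conc must be a non-negative finite number", call. = FALSE)
  }
  if (!is.finite(protein0) || protein0 <= 0) {
    stop("protein0 must be positive", call. = FALSE)
  }
  structure(list(el_conc = el_conc, protein0 = protein0,
                 temperature_c = temperature_c, urea_m = urea_m),
            class = "experiment_condition")
}

#' Integrate the capture kinetic scheme
#'
#' Solves the mass-action system
#' \deqn{dN/dt = -k_u N + k_f I}
#' \deqn{dI/dt = k_u N - k_f I - k_c [EL] I - 2 k_{agg} I^2}
#' \deqn{dC/dt = k_c [EL] I}
#' \deqn{dA/dt = 2 k_{agg} I^2}
#' from N(0) = protein0, I(0) = C(0) = A(0) = 0, with a stiff-safe
#' integrator (relative tolerance 1e-8, absolute 1e-10 uM). The soluble
#' pool observed in the supernatant after the bead spin is N + I;
#' captured (C) and aggregated (A, monomer units) material is removed.
#'
#' @param params A [capture_params()] object.
#' @param cond An [experiment_condition()] object.
#' @param times Output times in minutes, starting at 0, strictly increasing.
#' @return A data frame of class `species_trajectory` with columns
#'   `time_min`, `n_uM`, `i_uM`, `c_uM`, `a_uM`, `soluble_frac`.
#' @examples
#' p <- capture_params(0.03, 0.3, 0.35, 0.02)
#' traj <- simulate_capture(p, experiment_condition(3), seq(0, 60, 1))
#' tail(traj, 1)$soluble_frac  # ~0.25 of starting material still soluble
#' @export
simulate_capture <- function(params, cond, times = seq(0, 60, by = 1)) {
  stopifnot(inherits(params, "capture_params"),
            inherits(cond, "experiment_condition"))
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  }
  el <- cond$el_conc
  deriv <- function(t, y, parms) {
    flux_u <- parms$k_u * y[["N"]]
    flux_f <- parms$k_f * y[["I"]]
    flux_c <- parms$k_c * el * y[["I"]]
    flux_a <- 2 * parms$k_agg * y[["I"]]^2
    list(c(N = -flux_u + flux_f,
           I = flux_u - flux_f - flux_c - flux_a,
           C = flux_c,
           A = flux_a))
  }
  y0 <- c(N = cond$protein0, I = 0, C = 0, A = 0)
  sol <- deSolve::lsoda(y0, times, deriv, params,
                        rtol = 1e-8, atol = 1e-10)
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop("ODE integration failed (lsoda istate ", diag[1], ")",
         call. = FALSE)
  }
  sol <- as.data.frame(sol)
  out <- data.frame(time_min = sol$time,
                    n_uM = sol$N, i_uM = sol$I,
                    c_uM = sol$C, a_uM = sol$A,
                    soluble_frac = (sol$N + sol$I) / cond$protein0)
  attr(out, "condition") <- cond
  attr(out, "params") <- params
  class(out) <- c("species_trajectory", "data.frame")
  out
}

#' Closed-form apparent partitioning rate
#'
#' Under the rapid pre-equilibrium / steady-state treatment of the
#' intermediate, the soluble pool decays as a single exponential with
#' apparent rate
#' \deqn{k_{app} = \frac{k_u k_c [EL]}{k_f + k_c [EL]}}
#' which rises hyperbolically with chaperonin concentration and saturates
#' at the unfolding rate `k_u` (unfolding becomes rate limiting).
#'
#' @param params A [capture_params()] object.
#' @param el_conc Chaperonin oligomer concentration (uM); may be a vector.
#' @return Apparent rate(s) in min^-1.
#' @examples
#' apparent_rate(capture_params(0.03, 0.3, 0.35), 3)  # 0.02333 min^-1
#' @export
apparent_rate <- function(params, el_conc) {
  stopifnot(inherits(params, "capture_params"))
  if (any(el_conc < 0)) stop("el_conc must be non-negative", call. = FALSE)
  denom <- params$k_f + params$k_c * el_conc
  if (any(denom <= 0)) {
    stop("k_f + k_c*[EL] must be positive for the apparent rate",
         call. = FALSE)
  }
  params$k_u * params$k_c * el_conc / denom
}

#' Write a species trajectory to CSV
#'
#' @param traj A trajectory from [simulate_capture()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "species_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
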