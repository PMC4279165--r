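# In vivo solubility arithmetic from SDS-PAGE band densitometry:
# fraction soluble S/(S+P) per replicate, triplicate summary, and log2
# fold change against the no-additive control.

#' Fraction of protein in the soluble band
#'
#' @param s_band Soluble-fraction band intensity (arbitrary density
#'   units), non-negative.
#' @param p_band Pellet-fraction band intensity, non-negative. At least
#'   one band must be positive.
#' @return `s_band / (s_band + p_band)`, vectorized.
#' @export
fraction_soluble <- function(s_band, p_band) {
  if (any(s_band < 0) || any(p_band < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  if (any(s_band + p_band == 0)) {
    stop("both bands are zero: fraction undefined", call. = FALSE)
  }
  s_band / (s_band + p_band)
}

#' Summarize replicate densitometry for one condition
#'
#' @param records A data frame with columns `s_band` and `p_band`, one
#'   row per replicate (n = 3 in the standard design).
#' @return An object of class `solubility_result` with `fraction_soluble`
#'   (replicate mean), `sd` (n-1 denominator) and `n`.
#' @export
summarize_solubility <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("s_band", "p_band") %in% names(records)))
  fr <- fraction_soluble(records$s_band, records$p_band)
  structure(list(fraction_soluble = mean(fr),
                 sd = stats::sd(fr), n = length(fr)),
            class = "solubility_result")
}

#' Log2 solubility ratio versus control
#'
#' Log2 of the ratio between the soluble fraction in a condition (e.g.
#' osmolyte added to the growth medium) and the matched control;
#' positive values mean the additive increased the expressed soluble
#' fraction.
#'
#' @param cond,control `solubility_result` objects (or lists with a
#'   `fraction_soluble` element). The control fraction must be positive.
#' @return The log2 ratio.
#' @export
log2_solubility_ratio <- function(cond, control) {
  fc <- cond$fraction_soluble
  f0 <- control$fraction_soluble
  if (!is.finite(f0) || f0 <= 0) {
    stop("control soluble fraction must be positive", call. = FALSE)
  }
  log2(fc / f0)
}

#' Per-condition solubility table from a densitometry data frame
#'
#' @param dens Data frame with columns `variant`, `condition`,
#'   `replicate`, `s_band`, `p_band`.
#' @param control Name of the control condition (default "control").
#' @return Data frame with one row per (variant, condition):
#'   `fraction_soluble`, `sd`, `n`, `log2_ratio` (NA for the control row).
#' @export
solubility_table <- function(dens, control = "control") {
  stopifnot(all(c("variant", "condition", "s_band", "p_band") %in%
                  names(dens)))
  out <- do.call(rbind, lapply(split(dens, dens[c("variant", "condition")],
                                     drop = TRUE), function(g) {
    sm <- summarize_solubility(g)
    data.frame(variant = g$variant[1], condition = g$condition[1],
               fraction_soluble = sm$fraction_soluble, sd = sm$sd,
               n = sm$n)
  }))
  rownames(out) <- NULL
  out$log2_ratio <- NA_real_
  for (v in unique(out$variant)) {
    ctrl <- out[out$variant == v & out$condition == control, ]
    if (nrow(ctrl) != 1 || ctrl$fraction_soluble <= 0) next
    sel <- out$variant == v & out$condition != control
    out$log2_ratio[sel] <- log2(out$fraction_soluble[sel] /
                                  ctrl$fraction_soluble)
  }
  out
}
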