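# CSV readers/writers for the documented long-format schemas, run
# configuration, and the end-to-end synthetic analysis driver. All CSVs
# are UTF-8 with "." as the decimal separator.

#' Read soluble-fraction time courses from a long-format CSV
#'
#' Expected columns: `el_uM`, `time_min`, `soluble_frac` and optionally
#' `sd`; one row per point, grouped by chaperonin concentration. Rows
#' violating the schema are reported by row number.
#'
#' @param path CSV file path.
#' @param protein0 Starting protein concentration (uM) recorded in each
#'   returned condition.
#' @return A named list of [time_course()] objects, one per `el_uM`.
#' @export
read_timecourse_csv <- function(path, protein0 = 2) {
  df <- utils::read.csv(path)
  need <- c("el_uM", "time_min", "soluble_frac")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty time-course file", call. = FALSE)
  bad <- which(df$soluble_frac < 0 | df$soluble_frac > 1.1)
  if (length(bad)) {
    stop("soluble_frac out of [0, 1.1] at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$el_uM), function(g) {
    g <- g[order(g$time_min), ]
    if (any(duplicated(g$time_min))) {
      stop("repeated times within el_uM = ", g$el_uM[1], call. = FALSE)
    }
    time_course(g$time_min, g$soluble_frac,
                sd = if ("sd" %in% names(g)) g$sd else NULL,
                condition = experiment_condition(g$el_uM[1], protein0))
  })
}

#' Write time courses to the long-format CSV schema
#'
#' @param tcs A list of [time_course()] objects with conditions attached.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tcs, path) {
  rows <- do.call(rbind, lapply(tcs, function(tc) {
    data.frame(el_uM = attr(tc, "condition")$el_conc,
               time_min = tc$time_min,
               soluble_frac = tc$soluble_frac,
               sd = if (!is.null(tc$sd)) tc$sd else NA_real_)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a melt curve from CSV (`temp_c`, `signal` columns)
#'
#' @param path CSV file path.
#' @param ... Metadata passed to [melt_curve()].
#' @return A [melt_curve()].
#' @export
read_meltcurve_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  if (!all(c("temp_c", "signal") %in% names(df))) {
    stop("melt-curve CSV needs temp_c and signal columns", call. = FALSE)
  }
  df <- df[order(df$temp_c), ]
  melt_curve(df$temp_c, df$signal, ...)
}

#' Run configuration for the end-to-end analysis
#'
#' @param el_concs Chaperonin oligomer concentrations (uM) for the
#'   partitioning series.
#' @param protein0_partition Starting protein for partitioning (uM).
#' @param protein0_dsf Protein concentration in the DSF assay (uM,
#'   metadata).
#' @param temperature_c Partitioning assay temperature (Celsius).
#' @param urea_m Molar urea in the partitioning buffer.
#' @param buffer Buffer description (metadata).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param noise_sd Time-course noise SD.
#' @param dsf_noise_frac DSF noise as a fraction of amplitude.
#' @return A list of class `run_config`.
#' @export
run_config <- function(el_concs = c(0.5, 1, 2, 3, 6, 12),
                       protein0_partition = 2, protein0_dsf = 4,
                       temperature_c = 45, urea_m = 1,
                       buffer = paste("50 mM Tris, 50 mM KCl, 5 mM MgCl2,",
                                      "0.5 mM EDTA, 1 mM DTT, pH 7.5"),
                       seed = 1, noise_sd = 0.02, dsf_noise_frac = 0.01) {
  if (length(el_concs) < 3 || any(el_concs < 0)) {
    stop("el_concs must list at least 3 non-negative concentrations",
         call. = FALSE)
  }
  structure(list(el_concs = el_concs,
                 protein0_partition = protein0_partition,
                 protein0_dsf = protein0_dsf,
                 temperature_c = temperature_c, urea_m = urea_m,
                 buffer = buffer, seed = seed, noise_sd = noise_sd,
                 dsf_noise_frac = dsf_noise_frac),
            class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates synthetic inputs from the variant presets under the given
#' configuration and runs every analysis stage: per-concentration decay
#' fits and the rate-saturation fit for the two partition-prone variants,
#' DSF two-state fits for all three variants, aggregation QC on a pair of
#' synthetic spectra, and a solubility table from synthetic densitometry.
#' Deterministic for a fixed config seed. A failure in one stage is
#' recorded in `errors` without aborting the others.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, a JSON report and CSV
#'   tables are written there.
#' @return A list of class `capture_report`.
#' @export
run_full_analysis <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(schema_version = "1.0",
                 package_version =
                   as.character(utils::packageVersion("foldtrap")),
                 seed = config$seed, errors = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors <<- c(report$errors,
                          paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  # kinetic partitioning: decay fits and saturation per variant
  report$partition <- stage("partition", {
    out <- list()
    for (v in c("I154F", "D122Y")) {
      pre <- preset(v)
      tcs <- lapply(seq_along(config$el_concs), function(i) {
        gen_timecourse(pre,
                       experiment_condition(config$el_concs[i],
                                            config$protein0_partition,
                                            config$temperature_c,
                                            config$urea_m),
                       noise_sd = config$noise_sd,
                       seed = config$seed + 97 * i +
                         1000 * match(v, c("I154F", "D122Y")))
      })
      prof <- profile_from_timecourses(tcs)
      sat <- fit_rate_saturation(prof)
      out[[v]] <- list(profile = as.data.frame(prof),
                       k_max = sat$k_max, k_half = sat$k_half,
                       saturation_not_reached = sat$saturation_not_reached)
    }
    out
  })

  # DSF fits for the three variants
  report$dsf <- stage("dsf", {
    fits <- lapply(preset_names(), function(v) {
      cur <- gen_meltcurve(preset(v), noise_frac = config$dsf_noise_frac,
                           seed = config$seed + 7 +
                             match(v, preset_names()))
      f <- fit_melt(cur)
      list(variant = v, tm = f$tm, tm_se = f$tm_se, dh_vh = f$dh_vh)
    })
    names(fits) <- preset_names()
    fits
  })

  # aggregation QC: clean t0 spectrum vs scattering t60 spectrum
  report$aggregation_qc <- stage("aggregation_qc", {
    s0 <- gen_spectrum(0.3, 0, seed = config$seed + 31, label = "t0")
    s60 <- gen_spectrum(0.3, 0.05, seed = config$seed + 32, label = "t60")
    qc <- aggregation_index(s60, s0)
    list(delta_a350 = qc$delta_a350, aggregating = qc$aggregating,
         corrected_a280_t0 = baseline_corrected_a280(s0))
  })

  # solubility table from synthetic densitometry
  report$solubility <- stage("solubility", {
    dens <- rbind(
      gen_densitometry(0.5, seed = config$seed + 41, variant = "D122Y",
                       condition = "control"),
      gen_densitometry(0.75, seed = config$seed + 42, variant = "D122Y",
                       condition = "TMAO_0.5M"),
      gen_densitometry(0.2, seed = config$seed + 43, variant = "I154F",
                       condition = "control"),
      gen_densitometry(0.35, seed = config$seed + 44, variant = "I154F",
                       condition = "TMAO_0.5M"))
    solubility_table(dens)
  })

  class(report) <- c("capture_report", "list")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$solubility)) {
      utils::write.csv(report$solubility,
                       file.path(outdir, "solubility.csv"),
                       row.names = FALSE)
    }
  }
  report
}

#' @export
print.capture_report <- function(x, ...) {
  cat("Chaperonin-capture analysis report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$partition)) {
    for (v in names(x$partition)) {
      cat(sprintf("  %s: limiting rate k_max = %.4g min^-1 (k_half = %.3g uM)\n",
                  v, x$partition[[v]]$k_max, x$partition[[v]]$k_half))
    }
  }
  if (!is.null(x$dsf)) {
    for (v in names(x$dsf)) {
      cat(sprintf("  %s DSF Tm = %.2f degC\n", v, x$dsf[[v]]$tm))
    }
  }
  if (length(x$errors)) {
    cat("  stage errors:\n")
    for (e in x$errors) cat("   -", e, "\n")
  }
  invisible(x)
}

#' Published DSF melting-temperature table
#'
#' Loads the bundled CSV of published DSF melting temperatures for the
#' three frataxin variants across trehalose and TMAO concentrations,
#' together with the printed melting-temperature shifts. Rows whose
#' printed shift does not equal Tm minus the printed control Tm (within
#' `tol`) are marked `inconsistent = TRUE`: several published shift
#' entries do not match their own control column, and this loader
#' surfaces rather than silently corrects them.
#'
#' @param tol Consistency tolerance in Celsius (default 0.05, i.e.
#'   printed precision).
#' @return Data frame with columns `variant`, `osmolyte`, `conc_M`,
#'   `tm_c`, `tm_err`, `dtm_printed`, `dtm_computed`, `inconsistent`.
#' @export
dsf_tm_table <- function(tol = 0.05) {
  path <- system.file("extdata", "dsf_tm_table.csv", package = "foldtrap")
  df <- utils::read.csv(path)
  ctrl <- df[df$osmolyte == "none", c("variant", "tm_c")]
  names(ctrl)[2] <- "control_tm"
  df <- merge(df, ctrl, by = "variant", sort = FALSE)
  df$dtm_computed <- df$tm_c - df$control_tm
  df$inconsistent <- !is.na(df$dtm_printed) &
    abs(df$dtm_printed - df$dtm_computed) > tol + 1e-9
  df[order(df$variant, df$osmolyte, df$conc_M), ]
}
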