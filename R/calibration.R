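# Expert-system calibration of the EHI component rating functions.
#
# The corrected scheme replaces the categorical TI/EI tables by continuous
# fits to expert-panel ratings: a power law in the OEL for TI (doubling per
# tenfold OEL decrease), a linear regression in exposure duration for EI,
# and corrected lookups for MI and PI.

.pkg_env <- new.env(parent = emptyenv())

#' Fit the toxicity-index scale constant
#'
#' The corrected toxicity index follows `TI = K0 * 2^(-log10(OEL))`: each
#' tenfold increase in a chemical's OEL-TWA halves its toxicity rating.
#' Taking log2 of both sides makes the model linear with known slope, so K0
#' has the closed-form least-squares solution
#' `log2(K0) = mean(log2(rating) + log10(oel))`.
#'
#' @param oel Positive OEL-TWA values in ppm.
#' @param rating Positive TI ratings at those OELs.
#' @return The scale constant K0 (positive scalar).
#' @examples
#' tab <- expert_ratings()$ti
#' fit_ti_scale(tab$oel_twa, tab$corrected)   # ~17.88
#' @export
fit_ti_scale <- function(oel, rating) {
  if (length(oel) == 0L || length(oel) != length(rating)) {
    stop("'oel' and 'rating' must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(oel) | oel <= 0) || any(!is.finite(rating) | rating <= 0)) {
    stop("all OELs and ratings must be positive and finite", call. = FALSE)
  }
  2^mean(log2(rating) + log10(oel))
}

#' Ordinary least-squares line fit
#'
#' Thin wrapper around [stats::lm()] returning just the line coefficients,
#' with an optional through-origin constraint.
#'
#' @param x,y Numeric vectors of equal length (at least two distinct `x`).
#' @param through_origin Force the intercept to zero.
#' @return A list with `slope` and `intercept`.
#' @examples
#' fit_linear(c(0, 1), c(0, 1))   # slope 1, intercept 0
#' @export
fit_linear <- function(x, y, through_origin = FALSE) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("need at least two (x, y) pairs", call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("'x' values are degenerate (all identical)", call. = FALSE)
  }
  if (through_origin) {
    fit <- stats::lm(y ~ 0 + x)
    list(slope = unname(stats::coef(fit)[["x"]]), intercept = 0)
  } else {
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    list(slope = unname(cf[["x"]]), intercept = unname(cf[["(Intercept)"]]))
  }
}

check_expert_tables <- function(tables) {
  required <- list(ti = c("oel_twa", "mean"), ei = c("minutes", "mean"),
                   mi = c("n_measures", "mean"),
                   pi = c("engineering", "ppe", "mean"))
  missing <- character(0)
  for (nm in names(required)) {
    tab <- tables[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) {
      missing <- c(missing, nm)
    } else if (!all(required[[nm]] %in% names(tab))) {
      missing <- c(missing, sprintf("%s (columns %s)", nm,
                                    paste(setdiff(required[[nm]], names(tab)),
                                          collapse = ", ")))
    }
  }
  if (length(missing)) {
    stop("expert tables incomplete; missing or empty: ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  invisible(tables)
}

#' Fit the corrected EHI calibration from expert rating tables
#'
#' Assembles the full parameter set of the corrected scheme:
#' \itemize{
#'   \item TI: power-law scale constant K0 from [fit_ti_scale()].  By default
#'     the fit uses the published corrected TI column (`ti_source =
#'     "corrected"`), which the power law reproduces self-consistently; set
#'     `ti_source = "panel"` to fit the raw panel means of a user-supplied
#'     table.
#'   \item EI: linear regression of panel mean ratings on exposure duration
#'     (minutes), via [fit_linear()]; predictions are clamped to \[0, 1\].
#'   \item MI: the corrected lookup over N = 0..4 (`mi_source = "corrected"`).
#'     With `mi_source = "fit"` the lookup is rebuilt by regressing the panel
#'     means over N = 1..4 and predicting N = 0..4, capped to \[0, 1\] — the
#'     published corrected values keep MI(0) > 0, so the fit deliberately
#'     excludes the N = 0 panel row.
#'   \item PI: lookup of the corrected column (equal to the panel means for
#'     the built-in tables) over the six engineering/PPE combinations.
#' }
#'
#' @param tables Expert rating tables as returned by [expert_ratings()]; a
#'   named list of data frames `ti`, `ei`, `mi`, `pi`.  Tables without a
#'   `corrected` column fall back to their `mean` column where a corrected
#'   value is called for.
#' @param ti_source `"corrected"` (default) or `"panel"` — which TI column
#'   to fit K0 on.
#' @param ei_through_origin Force the EI regression through the origin.
#' @param mi_source `"corrected"` (lookup) or `"fit"` (regression rebuild).
#' @param pdi_formula PDI formula passed to [compute_pdi()].
#' @param carcinogen_ti `"extrapolate"` (default): rate carcinogen/no-OEL
#'   agents by substituting the effective OEL of 0.001 ppm into the power
#'   law; `"pin"`: pin their corrected TI at 128, the original scheme's
#'   maximum level.
#' @return An object of class `ehi_calibration` with components `k0`,
#'   `ei_slope`, `ei_intercept`, `mi_table`, `pi_table`, `pdi_formula`,
#'   `carcinogen_ti`.
#' @seealso [predict.ehi_calibration()], [rate_ti()], [write_calibration()]
#' @examples
#' cal <- ehi_calibration()
#' coef(cal)
#' rate_mi(0, "corrected", cal)   # 0.18
#' @export
ehi_calibration <- function(tables = expert_ratings(),
                            ti_source = c("corrected", "panel"),
                            ei_through_origin = FALSE,
                            mi_source = c("corrected", "fit"),
                            pdi_formula = c("average", "product_complement",
                                            "sum_complement"),
                            carcinogen_ti = c("extrapolate", "pin")) {
  ti_source <- match.arg(ti_source)
  mi_source <- match.arg(mi_source)
  pdi_formula <- match.arg(pdi_formula)
  carcinogen_ti <- match.arg(carcinogen_ti)
  check_expert_tables(tables)

  corrected_col <- function(tab) {
    if ("corrected" %in% names(tab)) tab$corrected else tab$mean
  }

  ti_tab <- tables$ti
  ti_ratings <- if (ti_source == "corrected") corrected_col(ti_tab) else ti_tab$mean
  k0 <- fit_ti_scale(ti_tab$oel_twa, ti_ratings)

  ei_fit <- fit_linear(tables$ei$minutes, tables$ei$mean,
                       through_origin = ei_through_origin)

  mi_tab <- tables$mi
  if (mi_source == "corrected") {
    mi_vals <- corrected_col(mi_tab)
    mi_table <- stats::setNames(mi_vals, as.character(mi_tab$n_measures))
    mi_table <- mi_table[as.character(0:4)]
    if (anyNA(mi_table)) {
      stop("MI table must cover N = 0..4", call. = FALSE)
    }
    mi_fit <- fit_linear(mi_tab$n_measures[mi_tab$n_measures >= 1],
                         mi_tab$mean[mi_tab$n_measures >= 1])
  } else {
    keep <- mi_tab$n_measures >= 1
    mi_fit <- fit_linear(mi_tab$n_measures[keep], mi_tab$mean[keep])
    mi_table <- stats::setNames(
      pmin(1, pmax(0, mi_fit$intercept + mi_fit$slope * (0:4))),
      as.character(0:4))
  }

  pi_tab <- tables$pi
  pi_table <- stats::setNames(corrected_col(pi_tab),
                              paste(pi_tab$engineering, pi_tab$ppe, sep = "+"))
  pi_table <- pi_table[names(.pi_original)]
  if (anyNA(pi_table)) {
    stop("PI table must cover all six engineering/PPE combinations",
         call. = FALSE)
  }

  structure(
    list(k0 = k0,
         ei_slope = ei_fit$slope, ei_intercept = ei_fit$intercept,
         ei_through_origin = ei_through_origin,
         mi_table = mi_table, mi_slope = mi_fit$slope,
         mi_intercept = mi_fit$intercept,
         pi_table = pi_table,
         pdi_formula = pdi_formula, carcinogen_ti = carcinogen_ti,
         ti_source = ti_source, mi_source = mi_source),
    class = "ehi_calibration"
  )
}

#' Default corrected calibration
#'
#' The calibration fitted once from the built-in expert tables
#' ([expert_ratings()]) with all default options; cached for the session.
#'
#' @return An [ehi_calibration()] object.
#' @export
default_calibration <- function() {
  if (is.null(.pkg_env$default_cal)) {
    .pkg_env$default_cal <- ehi_calibration()
  }
  .pkg_env$default_cal
}

#' @export
print.ehi_calibration <- function(x, digits = 4, ...) {
  cat("Corrected EHI calibration\n")
  cat(sprintf("  TI: K0 = %.*g (TI = K0 * 2^(-log10 OEL))\n", digits, x$k0))
  cat(sprintf("  EI: %.*g * minutes %+.*g, clamped to [0, 1]%s\n",
              digits, x$ei_slope, digits, x$ei_intercept,
              if (x$ei_through_origin) " (through origin)" else ""))
  cat("  MI lookup:", paste(sprintf("%d:%.2f", 0:4, x$mi_table), collapse = " "),
      "\n")
  cat("  PI lookup:", paste(sprintf("%s:%.2f", names(x$pi_table), x$pi_table),
                            collapse = " "), "\n")
  cat(sprintf("  PDI formula: %s; carcinogen TI: %s\n",
              x$pdi_formula, x$carcinogen_ti))
  invisible(x)
}

#' @export
coef.ehi_calibration <- function(object, ...) {
  c(k0 = object$k0, ei_slope = object$ei_slope,
    ei_intercept = object$ei_intercept, mi_slope = object$mi_slope,
    mi_intercept = object$mi_intercept)
}

#' @export
summary.ehi_calibration <- function(object, ...) {
  out <- list(coef = stats::coef(object), mi_table = object$mi_table,
              pi_table = object$pi_table, pdi_formula = object$pdi_formula,
              carcinogen_ti = object$carcinogen_ti)
  class(out) <- "summary.ehi_calibration"
  out
}

#' @export
print.summary.ehi_calibration <- function(x, ...) {
  cat("Corrected EHI calibration — fitted constants:\n")
  print(x$coef)
  cat("\nMI lookup (N = 0..4):\n"); print(x$mi_table)
  cat("\nPI lookup:\n"); print(x$pi_table)
  cat(sprintf("\nPDI formula: %s; carcinogen TI policy: %s\n",
              x$pdi_formula, x$carcinogen_ti))
  invisible(x)
}

#' Predict component indices and EHI for survey rows
#'
#' Applies the corrected rating functions to one enterprise-by-chemical row
#' per prediction.  `newdata` uses the survey schema columns (see
#' [read_survey_csv()]): `oel_twa_ppm`, `oel_ceiling_ppm`,
#' `carcinogen_no_oel`, `exposure_minutes`, `n_management`,
#' `engineering_control`, `ppe`.
#'
#' @param object An [ehi_calibration()].
#' @param newdata Data frame of survey rows.
#' @param scheme `"corrected"` (default) or `"original"`.
#' @param ... Unused.
#' @return `newdata` with columns `ti`, `ei`, `mi`, `pi`, `pdi`, `ehi`
#'   appended.
#' @export
predict.ehi_calibration <- function(object, newdata,
                                    scheme = c("corrected", "original"), ...) {
  scheme <- match.arg(scheme)
  rate_survey_rows(newdata, params = object, scheme = scheme)
}

#' Serialize a calibration to a YAML config file
#'
#' @param params An [ehi_calibration()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_calibration()]
#' @export
write_calibration <- function(params, path) {
  if (!inherits(params, "ehi_calibration")) {
    stop("'params' must be an ehi_calibration object", call. = FALSE)
  }
  cfg <- list(
    ti = list(k0 = params$k0, source = params$ti_source,
              carcinogen = params$carcinogen_ti),
    ei = list(slope = params$ei_slope, intercept = params$ei_intercept,
              through_origin = params$ei_through_origin),
    mi = list(table = as.list(params$mi_table), slope = params$mi_slope,
              intercept = params$mi_intercept, source = params$mi_source),
    pi = list(table = as.list(params$pi_table)),
    pdi = list(formula = params$pdi_formula)
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a calibration from a YAML config file
#'
#' @param path A file written by [write_calibration()] (or hand-edited in
#'   the same layout).
#' @return An [ehi_calibration()] object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    stop("calibration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  needed <- c("ti", "ei", "mi", "pi", "pdi")
  gap <- setdiff(needed, names(cfg))
  if (length(gap)) {
    stop("calibration config missing section(s): ", paste(gap, collapse = ", "),
         call. = FALSE)
  }
  mi_table <- unlist(cfg$mi$table)[as.character(0:4)]
  pi_table <- unlist(cfg$pi$table)[names(.pi_original)]
  if (anyNA(mi_table) || anyNA(pi_table)) {
    stop("calibration config MI/PI tables incomplete", call. = FALSE)
  }
  structure(
    list(k0 = cfg$ti$k0,
         ei_slope = cfg$ei$slope, ei_intercept = cfg$ei$intercept,
         ei_through_origin = isTRUE(cfg$ei$through_origin),
         mi_table = mi_table, mi_slope = cfg$mi$slope,
         mi_intercept = cfg$mi$intercept,
         pi_table = pi_table,
         pdi_formula = cfg$pdi$formula,
         carcinogen_ti = cfg$ti$carcinogen %||% "extrapolate",
         ti_source = cfg$ti$source %||% "corrected",
         mi_source = cfg$mi$source %||% "corrected"),
    class = "ehi_calibration"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read expert rating tables from a long-format CSV
#'
#' The CSV has one row per rated condition with columns `table` (one of
#' `ti`, `ei`, `mi`, `pi`), `predictor` (OEL-TWA in ppm for `ti`, minutes
#' for `ei`, N for `mi`, an `EEx+PPEx` combination string for `pi`),
#' `mean`, `sd` and optionally `corrected`.  The result has the shape of
#' [expert_ratings()] and feeds [ehi_calibration()].
#'
#' @param path CSV file path.
#' @return Named list of data frames `ti`, `ei`, `mi`, `pi`.
#' @examples
#' path <- system.file("extdata", "expert_ratings.csv", package = "ehiscore")
#' tabs <- read_expert_tables(path)
#' coef(ehi_calibration(tabs))
#' @export
read_expert_tables <- function(path) {
  if (!file.exists(path)) stop("expert table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("table", "predictor", "mean", "sd")
  gap <- setdiff(needed, names(df))
  if (length(gap)) {
    stop("expert table CSV missing column(s): ", paste(gap, collapse = ", "),
         call. = FALSE)
  }
  has_cor <- "corrected" %in% names(df)
  pick <- function(nm) {
    sub <- df[df$table == nm, , drop = FALSE]
    if (has_cor) sub else sub
  }
  add_cor <- function(out, sub) {
    if (has_cor) out$corrected <- sub$corrected
    out
  }
  ti <- pick("ti")
  ei <- pick("ei")
  mi <- pick("mi")
  pi <- pick("pi")
  combo <- strsplit(pi$predictor, "+", fixed = TRUE)
  tables <- list(
    ti = add_cor(data.frame(oel_twa = as.numeric(ti$predictor),
                            mean = ti$mean, sd = ti$sd), ti),
    ei = add_cor(data.frame(minutes = as.numeric(ei$predictor),
                            mean = ei$mean, sd = ei$sd), ei),
    mi = add_cor(data.frame(n_measures = as.integer(mi$predictor),
                            mean = mi$mean, sd = mi$sd), mi),
    pi = add_cor(data.frame(engineering = vapply(combo, `[`, "", 1),
                            ppe = vapply(combo, `[`, "", 2),
                            mean = pi$mean, sd = pi$sd,
                            stringsAsFactors = FALSE), pi)
  )
  check_expert_tables(tables)
  tables
}

#' Regress expert-panel enterprise EHI on model-corrected EHI
#'
#' Validation utility: given paired enterprise-level scores — the corrected
#' model's EHI and the expert panel's EHI for the same enterprises — fits
#' the ordinary least-squares line and reports slope, intercept and R².  A
#' slope near 1 and intercept near 0 indicate the corrected model tracks
#' the panel.
#'
#' @param ehi_cor Corrected-model enterprise EHI values.
#' @param ehi_es Expert-panel enterprise EHI values (same length, >= 2).
#' @return An object of class `ehi_validation`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.  R² is defined as 0 when the response
#'   has zero variance.
#' @examples
#' x <- c(1, 2, 5, 10)
#' validate_against_expert(x, 1.05 * x - 0.27)   # slope 1.05, R^2 = 1
#' @export
validate_against_expert <- function(ehi_cor, ehi_es) {
  n <- length(ehi_cor)
  if (n < 2L || length(ehi_es) != n) {
    stop("need at least two (ehi_cor, ehi_es) pairs of equal length",
         call. = FALSE)
  }
  if (stats::var(ehi_es) == 0) {
    fit <- fit_linear(ehi_cor, ehi_es)
    out <- list(slope = fit$slope, intercept = fit$intercept, r_squared = 0,
                n = n)
  } else {
    fit <- fit_linear(ehi_cor, ehi_es)
    resid <- ehi_es - (fit$intercept + fit$slope * ehi_cor)
    r2 <- 1 - sum(resid^2) / sum((ehi_es - mean(ehi_es))^2)
    out <- list(slope = fit$slope, intercept = fit$intercept,
                r_squared = max(0, min(1, r2)), n = n)
  }
  structure(out, class = "ehi_validation")
}

#' @export
print.ehi_validation <- function(x, ...) {
  cat(sprintf("EHI_panel = %.3f * EHI_model %+.3f  (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
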