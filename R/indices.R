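# Component rating functions of the Exposure Hazard Index.  Each index can
# be rated under the "original" categorical tables or the "corrected"
# (expert-system-calibrated) continuous scheme.  EHI = TI * EI * PDI, with
# PDI combining the management (MI) and protection (PI) indices.

.schemes <- c("original", "corrected")

resolve_params <- function(params, scheme) {
  if (scheme == "original") return(params)
  if (is.null(params)) return(default_calibration())
  if (!inherits(params, "ehi_calibration")) {
    stop("'params' must be an ehi_calibration object", call. = FALSE)
  }
  params
}

#' Toxicity index (TI) of a chemical
#'
#' Rates toxicity from the effective OEL-TWA.  The original scheme assigns
#' one of eight doubling levels 1, 2, 4, ..., 128 over decade bands of the
#' OEL-TWA (lower bound exclusive, upper inclusive; above 1,000 ppm rates 1,
#' at or below 0.001 ppm rates 128).  The corrected scheme is the continuous
#' power law `TI = K0 * 2^(-log10(OEL))` fitted to expert-panel ratings: a
#' tenfold drop in the OEL doubles the index.
#'
#' @param agent A [chemical_agent()], or directly a vector of positive
#'   effective OEL-TWA values in ppm.
#' @param scheme `"original"` or `"corrected"`.
#' @param params An [ehi_calibration()] for the corrected scheme; defaults to
#'   the calibration fitted from the built-in expert tables.
#' @return TI rating(s): in the original scheme one of
#'   `c(1, 2, 4, 8, 16, 32, 64, 128)`; in the corrected scheme a positive
#'   real.
#' @examples
#' rate_ti(chemical_agent("TDI", oel_twa = 0.005), "original")   # 64
#' rate_ti(chemical_agent("DMF", oel_twa = 10), "corrected")     # ~8.94
#' @export
rate_ti <- function(agent, scheme = c("original", "corrected"), params = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(agent, "chemical_agent")) {
    if (scheme == "corrected" && isTRUE(agent$no_oel_or_carcinogen) &&
        is.na(agent$oel_twa) && is.na(agent$oel_ceiling)) {
      params <- resolve_params(params, scheme)
      if (identical(params$carcinogen_ti, "pin")) return(128)
    }
    oel <- effective_oel(agent)
  } else {
    oel <- as.numeric(agent)
  }
  if (length(oel) == 0L || any(!is.finite(oel) | oel <= 0)) {
    stop("effective OEL must be positive and finite", call. = FALSE)
  }
  if (scheme == "original") {
    # level k covers 10^(3-k) >= OEL > 10^(2-k); idx counts bands crossed
    thresholds <- 10^(3:-3)
    idx <- vapply(oel, function(x) sum(x <= thresholds), numeric(1))
    2^idx
  } else {
    params <- resolve_params(params, scheme)
    params$k0 * 2^(-log10(oel))
  }
}

#' Exposure index (EI) from daily exposure duration
#'
#' The original scheme is a three-level band over the daily exposure
#' duration: 0.30 below 2 h, 0.60 from 2 h to below 4 h, and 1.00 at 4 h or
#' more.  The corrected scheme is a linear regression of expert-panel
#' ratings on duration, clamped to \[0, 1\].
#'
#' @param minutes Exposure duration(s) in minutes (non-negative).
#' @inheritParams rate_ti
#' @return EI rating(s) in \[0, 1\].
#' @examples
#' rate_ei(225, "original")   # 0.60
#' rate_ei(48, "corrected")   # ~0.11
#' @export
rate_ei <- function(minutes, scheme = c("original", "corrected"), params = NULL) {
  scheme <- match.arg(scheme)
  minutes <- as.numeric(minutes)
  if (length(minutes) == 0L || any(!is.finite(minutes) | minutes < 0)) {
    stop("exposure duration must be finite, non-negative minutes", call. = FALSE)
  }
  if (scheme == "original") {
    ifelse(minutes < 120, 0.30, ifelse(minutes < 240, 0.60, 1.00))
  } else {
    params <- resolve_params(params, scheme)
    ei <- params$ei_intercept + params$ei_slope * minutes
    pmin(1, pmax(0, ei))
  }
}

#' Management index (MI) from the number of implemented measures
#'
#' Counts how many of the four management measures (safety/health personnel,
#' material safety data sheets, standard operating procedures, training) a
#' workplace implements.  The original scheme rates N/4; the corrected
#' scheme is the expert-derived lookup, which is non-zero even at N = 0
#' (basic hygiene knowledge offers some protection).
#'
#' @param n_measures Integer count(s) of implemented measures, 0–4.
#' @inheritParams rate_ti
#' @return MI rating(s) in \[0, 1\].
#' @examples
#' rate_mi(2, "original")    # 0.50
#' rate_mi(0, "corrected")   # 0.18
#' @export
rate_mi <- function(n_measures, scheme = c("original", "corrected"),
                    params = NULL) {
  scheme <- match.arg(scheme)
  n <- as.numeric(n_measures)
  if (length(n) == 0L || any(is.na(n) | n %% 1 != 0 | n < 0 | n > 4)) {
    stop("number of management measures must be integers between 0 and 4",
         call. = FALSE)
  }
  if (scheme == "original") {
    n / 4
  } else {
    params <- resolve_params(params, scheme)
    unname(params$mi_table[as.character(as.integer(n))])
  }
}

#' Protection index (PI) from the engineering/PPE control combination
#'
#' Rates the combination of engineering controls — effective (`EEe`:
#' enclosure or local exhaust), partially effective (`EEp`: general
#' ventilation), none (`EEn`) — with personal protective equipment provision
#' (`PPEe` provided, `PPEn` not).
#'
#' @param engineering `"EEe"`, `"EEp"` or `"EEn"` (vectorized).
#' @param ppe `"PPEe"` or `"PPEn"` (vectorized).
#' @inheritParams rate_ti
#' @return PI rating(s) in \[0, 1\].
#' @examples
#' rate_pi("EEp", "PPEe", "original")    # 0.50
#' rate_pi("EEp", "PPEe", "corrected")   # 0.61
#' @export
rate_pi <- function(engineering, ppe, scheme = c("original", "corrected"),
                    params = NULL) {
  scheme <- match.arg(scheme)
  if (length(engineering) != length(ppe)) {
    stop("'engineering' and 'ppe' must have equal length", call. = FALSE)
  }
  if (any(!engineering %in% .engineering_levels)) {
    stop("engineering control must be one of EEe, EEp, EEn", call. = FALSE)
  }
  if (any(!ppe %in% .ppe_levels)) {
    stop("ppe must be one of PPEe, PPEn", call. = FALSE)
  }
  key <- paste(engineering, ppe, sep = "+")
  tab <- if (scheme == "original") {
    .pi_original
  } else {
    resolve_params(params, scheme)$pi_table
  }
  unname(tab[key])
}

#' Protection deficiency index (PDI) from MI and PI
#'
#' Combines the management and protection indices into the residual
#' exposure-probability factor of the EHI: PDI decreases as either index
#' improves, is 0 at full protection (MI = PI = 1) and 1 with none
#' (MI = PI = 0).  The exact functional form is configurable:
#' \describe{
#'   \item{`average`}{`1 - (MI + PI)/2` (default; affinely symmetric,
#'     bounded in \[0, 1\]).}
#'   \item{`product_complement`}{`(1 - MI) * (1 - PI)`.}
#'   \item{`sum_complement`}{`2 - MI - PI` (may exceed 1).}
#' }
#'
#' @param mi,pi Ratings in \[0, 1\] (vectorized).
#' @param formula PDI formula name.
#' @return PDI value(s).
#' @examples
#' compute_pdi(0.60, 0.42)   # 0.49
#' @export
compute_pdi <- function(mi, pi,
                        formula = c("average", "product_complement",
                                    "sum_complement")) {
  formula <- match.arg(formula)
  if (any(!is.finite(mi) | mi < 0 | mi > 1) ||
      any(!is.finite(pi) | pi < 0 | pi > 1)) {
    stop("'mi' and 'pi' must lie in [0, 1]", call. = FALSE)
  }
  switch(formula,
         average = 1 - (mi + pi) / 2,
         product_complement = (1 - mi) * (1 - pi),
         sum_complement = 2 - mi - pi)
}
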