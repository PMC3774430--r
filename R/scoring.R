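# Enterprise and industry scoring: per-chemical EHI = TI * EI * PDI, summed
# additively over an enterprise's chemicals; industries summarized by the
# 95th percentile of enterprise EHIs and banded into four control
# priorities at the 90th/70th/50th percentiles of the industry statistics.

agent_from_row <- function(row) {
  chemical_agent(
    name = as.character(row$chemical_name),
    oel_twa = if (is.null(row$oel_twa_ppm)) NA_real_ else row$oel_twa_ppm,
    oel_ceiling = if (is.null(row$oel_ceiling_ppm)) NA_real_ else row$oel_ceiling_ppm,
    no_oel_or_carcinogen = isTRUE(as.logical(row$carcinogen_no_oel)) ||
      identical(row$carcinogen_no_oel, 1) || identical(row$carcinogen_no_oel, 1L),
    cas = if (is.null(row$cas)) NA_character_ else as.character(row$cas)
  )
}

# Rate each enterprise-by-chemical survey row under a scheme; the workhorse
# behind predict.ehi_calibration(), score_enterprise() and score_survey().
rate_survey_rows <- function(rows, params = NULL, scheme = "corrected") {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("'newdata' must be a data frame with at least one row", call. = FALSE)
  }
  params <- resolve_params(params, scheme)
  pdi_formula <- if (scheme == "corrected") params$pdi_formula else "average"
  ti <- ei <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    agent <- agent_from_row(rows[i, , drop = FALSE])
    ti[i] <- rate_ti(agent, scheme, params)
    ei[i] <- rate_ei(rows$exposure_minutes[i], scheme, params)
  }
  mi <- rate_mi(rows$n_management, scheme, params)
  pi <- rate_pi(rows$engineering_control, rows$ppe, scheme, params)
  pdi <- compute_pdi(mi, pi, pdi_formula)
  out <- rows
  out$ti <- ti; out$ei <- ei; out$mi <- mi; out$pi <- pi; out$pdi <- pdi
  out$ehi <- ti * ei * pdi
  out
}

#' Score a single enterprise
#'
#' Computes the per-chemical index bundle (TI, EI, MI, PI, PDI, EHI) and the
#' enterprise total EHI.  Toxic effects are taken as additive: the
#' enterprise EHI is the plain sum of the per-chemical EHIs, with no
#' synergy or antagonism terms.
#'
#' @param exposures A data frame with one row per chemical exposure:
#'   `chemical_name`, `oel_twa_ppm`, `oel_ceiling_ppm` (either may be `NA`),
#'   `carcinogen_no_oel` (0/1), `exposure_minutes`.
#' @param n_management Number of implemented management measures, 0–4 (one
#'   value per enterprise).
#' @param engineering,ppe The enterprise's control profile
#'   (`EEe`/`EEp`/`EEn` and `PPEe`/`PPEn`).
#' @param params [ehi_calibration()] for the corrected scheme.
#' @param scheme `"corrected"` (default) or `"original"`.
#' @param enterprise_id Identifier used in error messages and output.
#' @return An object of class `enterprise_score`: list with
#'   `enterprise_id`, `indices` (per-chemical data frame) and `ehi_total`.
#'   An empty exposure table yields `ehi_total = 0`.
#' @examples
#' exp <- data.frame(chemical_name = "DMF", oel_twa_ppm = 10,
#'                   oel_ceiling_ppm = NA, carcinogen_no_oel = 0,
#'                   exposure_minutes = 225)
#' score_enterprise(exp, n_management = 2, engineering = "EEp", ppe = "PPEe")
#' @export
score_enterprise <- function(exposures, n_management, engineering, ppe,
                             params = NULL, scheme = c("corrected", "original"),
                             enterprise_id = "enterprise") {
  scheme <- match.arg(scheme)
  check_n_measures(n_management)
  check_engineering(engineering)
  check_ppe(ppe)
  if (is.null(exposures) || nrow(exposures) == 0L) {
    return(structure(list(enterprise_id = enterprise_id,
                          indices = data.frame(), ehi_total = 0),
                     class = "enterprise_score"))
  }
  rows <- exposures
  rows$n_management <- n_management
  rows$engineering_control <- engineering
  rows$ppe <- ppe
  scored <- tryCatch(
    rate_survey_rows(rows, params, scheme),
    error = function(e) {
      stop(sprintf("enterprise '%s': %s", enterprise_id, conditionMessage(e)),
           call. = FALSE)
    })
  structure(
    list(enterprise_id = enterprise_id,
         indices = scored[, c("chemical_name", "ti", "ei", "mi", "pi", "pdi",
                              "ehi")],
         ehi_total = sum(scored$ehi)),
    class = "enterprise_score"
  )
}

#' @export
print.enterprise_score <- function(x, ...) {
  cat(sprintf("<enterprise_score> %s: EHI total %.2f over %d chemical(s)\n",
              x$enterprise_id, x$ehi_total, nrow(x$indices)))
  if (nrow(x$indices)) {
    df <- x$indices
    df[-1] <- lapply(df[-1], round, 2)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Score every enterprise of a survey table
#'
#' @param survey A survey data frame in the schema of [read_survey_csv()]
#'   (one row per enterprise-by-chemical).
#' @inheritParams score_enterprise
#' @return Data frame of class `ehi_scores`: the survey rows with `ti`,
#'   `ei`, `mi`, `pi`, `pdi`, `ehi` and the per-enterprise `ehi_total`
#'   appended.
#' @export
score_survey <- function(survey, params = NULL,
                         scheme = c("corrected", "original")) {
  scheme <- match.arg(scheme)
  if (!is.data.frame(survey) || nrow(survey) == 0L) {
    stop("no enterprises: the survey table is empty", call. = FALSE)
  }
  scored <- rate_survey_rows(survey, params, scheme)
  scored$ehi_total <- stats::ave(scored$ehi, scored$enterprise_id, FUN = sum)
  class(scored) <- c("ehi_scores", "data.frame")
  scored
}

#' Linear-interpolation percentile
#'
#' The inclusive order-statistic percentile used throughout the priority
#' analysis: with the values sorted ascending, the p-th percentile sits at
#' rank `h = (n - 1) * p + 1`, linearly interpolated between the flanking
#' order statistics (identical to [stats::quantile()] type 7, R's default).
#'
#' @param values Non-empty numeric vector.
#' @param p Probability in \[0, 1\] (vectorized).
#' @return Percentile value(s).
#' @examples
#' ehi_percentile(c(1, 2, 3, 4, 5), 0.95)   # 4.8
#' @export
ehi_percentile <- function(values, p) {
  if (length(values) == 0L || anyNA(values)) {
    stop("'values' must be non-empty with no missing entries", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Mean and sample standard deviation
#'
#' @param values Numeric vector (length >= 2 for the standard deviation).
#' @return Named vector `c(mean, sd)` with the sample (n − 1 denominator)
#'   standard deviation.
#' @export
distribution_stats <- function(values) {
  if (length(values) < 2L) {
    stop("need at least two values for a sample standard deviation",
         call. = FALSE)
  }
  c(mean = mean(values), sd = stats::sd(values))
}

#' Summarize enterprise scores by industry
#'
#' Groups per-enterprise total EHIs by industry and reduces each group to a
#' single statistic — by default the 95th percentile of the enterprise
#' EHIs, the industry-level figure the national prioritization is based on.
#'
#' @param scores An `ehi_scores` data frame from [score_survey()] (needs
#'   `enterprise_id`, `industry_code`, `industry_name`, `ehi_total`).
#' @param statistic `"p95"` (default) or `"mean"`.
#' @return Data frame of class `industry_summary`: `industry_code`,
#'   `industry_name`, `n_enterprises`, `statistic`, `statistic_kind`,
#'   sorted by decreasing statistic.
#' @export
summarize_industries <- function(scores, statistic = c("p95", "mean")) {
  statistic <- match.arg(statistic)
  needed <- c("enterprise_id", "industry_code", "industry_name", "ehi_total")
  gap <- setdiff(needed, names(scores))
  if (length(gap)) {
    stop("scores table lacks column(s): ", paste(gap, collapse = ", "),
         call. = FALSE)
  }
  ent <- unique(scores[, needed])
  if (anyDuplicated(ent$enterprise_id)) {
    stop("inconsistent industry or total for some enterprise_id", call. = FALSE)
  }
  reduce <- if (statistic == "p95") {
    function(x) ehi_percentile(x, 0.95)
  } else {
    mean
  }
  split_by <- split(ent, ent$industry_code)
  out <- do.call(rbind, lapply(split_by, function(g) {
    data.frame(industry_code = g$industry_code[1],
               industry_name = g$industry_name[1],
               n_enterprises = nrow(g),
               statistic = reduce(g$ehi_total),
               statistic_kind = statistic,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$statistic, out$industry_code), ]
  rownames(out) <- NULL
  class(out) <- c("industry_summary", "data.frame")
  out
}

#' Assign four control-priority bands to industries
#'
#' Cutoffs are the 90th, 70th and 50th percentiles of the industry
#' statistics ([ehi_percentile()]).  Band boundaries are inclusive at the
#' lower cutoff: band 1 for statistic >= p90, band 2 for p70 <= statistic <
#' p90, band 3 for p50 <= statistic < p70, band 4 below p50.
#'
#' @param summaries An `industry_summary` data frame (or any data frame
#'   with `industry_code` and `statistic`), ideally >= 4 industries.
#' @return Object of class `ehi_priorities`: list with `cutoffs` (named
#'   `p90`, `p70`, `p50`) and `bands` (the summaries with a `band` column).
#' @examples
#' s <- data.frame(industry_code = sprintf("%02d", 1:5),
#'                 statistic = c(40, 25, 15, 8, 2))
#' assign_priorities(s)
#' @export
assign_priorities <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L) {
    stop("no industries to prioritize", call. = FALSE)
  }
  if (nrow(summaries) < 4L) {
    warning("fewer than 4 industries; priority bands will be coarse")
  }
  stat <- summaries$statistic
  cutoffs <- c(p90 = ehi_percentile(stat, 0.9),
               p70 = ehi_percentile(stat, 0.7),
               p50 = ehi_percentile(stat, 0.5))
  band <- ifelse(stat >= cutoffs["p90"], 1L,
                 ifelse(stat >= cutoffs["p70"], 2L,
                        ifelse(stat >= cutoffs["p50"], 3L, 4L)))
  bands <- as.data.frame(summaries)
  bands$band <- band
  structure(list(cutoffs = cutoffs, bands = bands), class = "ehi_priorities")
}

#' @export
print.ehi_priorities <- function(x, ...) {
  cat("Control-priority banding of industries\n")
  cat(sprintf("  cutoffs: p90 = %.2f, p70 = %.2f, p50 = %.2f\n",
              x$cutoffs["p90"], x$cutoffs["p70"], x$cutoffs["p50"]))
  sizes <- table(factor(x$bands$band, levels = 1:4))
  cat("  band sizes (1..4):", paste(as.integer(sizes), collapse = "/"), "\n")
  invisible(x)
}

#' Per-band profiles of the component indices
#'
#' For each priority band, summarizes the chemical-level TI, EI, MI and PI
#' ratings by mean, standard error and a mean ± 1.96 SE interval — the
#' diagnostic used to see which component drives a band's risk (e.g.
#' first-priority industries showing high EI with low MI and PI).
#'
#' @param scores An `ehi_scores` data frame from [score_survey()].
#' @param assignment An `ehi_priorities` object for the same survey.
#' @return Data frame with `band`, `index`, `n`, `mean`, `se`, `lower`,
#'   `upper` (one row per band-index pair; empty bands omitted with a
#'   warning).  SE is 0 for a single observation.
#' @export
band_index_profiles <- function(scores, assignment) {
  if (!inherits(assignment, "ehi_priorities")) {
    stop("'assignment' must come from assign_priorities()", call. = FALSE)
  }
  band_of <- stats::setNames(assignment$bands$band,
                             assignment$bands$industry_code)
  band <- band_of[as.character(scores$industry_code)]
  if (anyNA(band)) {
    stop("some scored industries are absent from the priority assignment",
         call. = FALSE)
  }
  empty <- setdiff(1:4, unique(band))
  if (length(empty)) {
    warning("empty priority band(s) omitted: ", paste(empty, collapse = ", "))
  }
  out <- do.call(rbind, lapply(sort(unique(band)), function(b) {
    sub <- scores[band == b, , drop = FALSE]
    do.call(rbind, lapply(c("ti", "ei", "mi", "pi"), function(ix) {
      v <- sub[[ix]]
      se <- if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
      data.frame(band = b, index = ix, n = length(v), mean = mean(v), se = se,
                 lower = mean(v) - 1.96 * se, upper = mean(v) + 1.96 * se,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
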