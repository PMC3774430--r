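# Survey CSV input/output and the end-to-end scoring pipeline.
#
# One row per enterprise-by-chemical; the management count and the
# engineering/PPE control profile are enterprise-level (every row of an
# enterprise must repeat them identically — the granularity of the national
# questionnaire).

.survey_columns <- c("enterprise_id", "industry_code", "industry_name",
                     "chemical_name", "cas", "oel_twa_ppm", "oel_ceiling_ppm",
                     "carcinogen_no_oel", "exposure_minutes", "n_management",
                     "engineering_control", "ppe")
.mgmt_bool_columns <- c("personnel", "msds", "sop", "training")

validate_survey_rows <- function(df) {
  reasons <- character(nrow(df))
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  twa <- num_or_na(df$oel_twa_ppm)
  ceil <- num_or_na(df$oel_ceiling_ppm)
  carc <- df$carcinogen_no_oel %in% c(1, "1", TRUE, "TRUE", "true")
  minutes <- num_or_na(df$exposure_minutes)
  nmg <- num_or_na(df$n_management)

  bad <- function(cond, why) {
    hit <- which(cond & !nzchar(reasons))
    reasons[hit] <<- why
  }
  bad(is.na(df$enterprise_id) | !nzchar(as.character(df$enterprise_id)),
      "missing enterprise_id")
  bad(is.na(df$chemical_name) | !nzchar(as.character(df$chemical_name)),
      "missing chemical_name")
  bad(!is.na(twa) & twa <= 0, "non-positive oel_twa_ppm")
  bad(!is.na(ceil) & ceil <= 0, "non-positive oel_ceiling_ppm")
  bad(is.na(twa) & is.na(ceil) & !carc,
      "no OEL and carcinogen_no_oel not set")
  bad(is.na(minutes) | minutes < 0 | !is.finite(minutes),
      "invalid exposure_minutes (negative or non-numeric)")
  bad(is.na(nmg) | nmg %% 1 != 0 | nmg < 0 | nmg > 4,
      "n_management outside 0..4")
  bad(!df$engineering_control %in% .engineering_levels,
      "unknown engineering_control")
  bad(!df$ppe %in% .ppe_levels, "unknown ppe")

  # enterprise-level profile consistency
  ok <- !nzchar(reasons)
  if (any(ok)) {
    prof <- paste(df$industry_code, df$n_management, df$engineering_control,
                  df$ppe)
    n_prof <- tapply(prof[ok], as.character(df$enterprise_id)[ok],
                     function(x) length(unique(x)))
    inconsistent <- names(n_prof)[n_prof > 1]
    bad(as.character(df$enterprise_id) %in% inconsistent,
        "inconsistent management/control profile within enterprise")
  }
  reasons
}

#' Read a survey CSV into a validated survey table
#'
#' Expected columns: `enterprise_id`, `industry_code`, `industry_name`,
#' `chemical_name`, `cas` (optional), `oel_twa_ppm`, `oel_ceiling_ppm`
#' (either may be empty), `carcinogen_no_oel` (0/1), `exposure_minutes`,
#' `engineering_control` (EEe/EEp/EEn), `ppe` (PPEe/PPEn), and either
#' `n_management` (0–4) or the four 0/1 measure columns `personnel`,
#' `msds`, `sop`, `training` (if both forms are present they must agree).
#'
#' @param path CSV file path.
#' @param strict If `TRUE`, any invalid row aborts with the offending line
#'   number; otherwise invalid rows are dropped and reported in the
#'   `rejections` attribute.
#' @return A data frame of class `ehi_survey` with attributes `source`,
#'   `n_rejected` and `rejections` (data frame of `line`, `reason`).
#' @export
read_survey_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(industry_code = "character"),
                        fileEncoding = "UTF-8")
  as_survey(df, strict = strict, source = path)
}

#' Validate a data frame as a survey table
#'
#' Applies the schema and row validation of [read_survey_csv()] to an
#' in-memory data frame.
#'
#' @param df Data frame in the survey schema.
#' @inheritParams read_survey_csv
#' @param source Provenance label stored on the result.
#' @return An `ehi_survey` data frame.
#' @export
as_survey <- function(df, strict = FALSE, source = "<memory>") {
  has_n <- "n_management" %in% names(df)
  has_bool <- all(.mgmt_bool_columns %in% names(df))
  if (!has_n && !has_bool) {
    stop("missing required column: n_management (or the four measure ",
         "columns personnel, msds, sop, training)", call. = FALSE)
  }
  if (has_bool) {
    bool_n <- Reduce(`+`, lapply(df[.mgmt_bool_columns],
                                 function(x) as.numeric(as.numeric(x) != 0)))
    if (has_n && any(as.numeric(df$n_management) != bool_n)) {
      stop("n_management disagrees with the personnel/msds/sop/training ",
           "columns", call. = FALSE)
    }
    if (!has_n) df$n_management <- bool_n
  }
  required <- setdiff(.survey_columns, c("cas", "oel_twa_ppm",
                                         "oel_ceiling_ppm"))
  gap <- setdiff(required, names(df))
  if (length(gap)) {
    stop("missing required column(s): ", paste(gap, collapse = ", "),
         call. = FALSE)
  }
  if (!"cas" %in% names(df)) df$cas <- NA_character_
  df$cas <- as.character(df$cas)
  if (!"oel_twa_ppm" %in% names(df)) df$oel_twa_ppm <- NA_real_
  if (!"oel_ceiling_ppm" %in% names(df)) df$oel_ceiling_ppm <- NA_real_
  df$industry_code <- as.character(df$industry_code)
  df$oel_twa_ppm <- suppressWarnings(as.numeric(df$oel_twa_ppm))
  df$oel_ceiling_ppm <- suppressWarnings(as.numeric(df$oel_ceiling_ppm))
  df$carcinogen_no_oel <- as.integer(df$carcinogen_no_oel %in%
                                       c(1, "1", TRUE, "TRUE", "true"))
  df$exposure_minutes <- suppressWarnings(as.numeric(df$exposure_minutes))
  df$n_management <- suppressWarnings(as.integer(df$n_management))

  reasons <- validate_survey_rows(df)
  bad <- nzchar(reasons)
  if (strict && any(bad)) {
    first <- which(bad)[1]
    stop(sprintf("invalid survey row %d (data line %d): %s",
                 first, first + 1L, reasons[first]), call. = FALSE)
  }
  rejections <- data.frame(line = which(bad) + 1L, reason = reasons[bad],
                           stringsAsFactors = FALSE)
  out <- df[!bad, .survey_columns, drop = FALSE]
  rownames(out) <- NULL
  structure(out, source = source, n_rejected = sum(bad),
            rejections = rejections, class = c("ehi_survey", "data.frame"))
}

#' Write a survey table to CSV
#'
#' Writes the canonical schema columns; [read_survey_csv()] of the result
#' reproduces the table (lossless round trip).
#'
#' @param survey An `ehi_survey` (or schema-compatible) data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  utils::write.csv(as.data.frame(survey)[, .survey_columns], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Run the full scoring and prioritization pipeline
#'
#' Deterministic composition of [score_survey()],
#' [summarize_industries()], [assign_priorities()] and
#' [band_index_profiles()], with a summary report of the industry-statistic
#' distribution and the band sizes.
#'
#' @param survey An `ehi_survey` data frame (see [read_survey_csv()]).
#' @param params [ehi_calibration()] for the corrected scheme (default: the
#'   built-in calibration).
#' @param scheme `"corrected"` (default) or `"original"`.
#' @param statistic Industry statistic, `"p95"` (default) or `"mean"`.
#' @return Object of class `ehi_pipeline`: list with `scores`,
#'   `industry_summary`, `priorities`, `profiles` and `report` (list with
#'   `n_enterprises`, `n_rows`, `mean`, `sd`, `band_sizes`, `cutoffs`).
#' @examples
#' survey <- generate_survey(generator_config(seed = 7,
#'   industries = industry_reference()[1:6, ]))
#' run_pipeline(survey)
#' @export
run_pipeline <- function(survey, params = NULL,
                         scheme = c("corrected", "original"),
                         statistic = c("p95", "mean")) {
  scheme <- match.arg(scheme)
  statistic <- match.arg(statistic)
  if (is.null(survey) || nrow(survey) == 0L) {
    stop("no enterprises: the survey table is empty", call. = FALSE)
  }
  scores <- score_survey(survey, params = params, scheme = scheme)
  summaries <- summarize_industries(scores, statistic = statistic)
  priorities <- assign_priorities(summaries)
  profiles <- band_index_profiles(scores, priorities)
  stat <- summaries$statistic
  ds <- if (length(stat) >= 2L) distribution_stats(stat) else
    c(mean = mean(stat), sd = NA_real_)
  band_sizes <- as.integer(table(factor(priorities$bands$band, levels = 1:4)))
  structure(
    list(scores = scores, industry_summary = summaries,
         priorities = priorities, profiles = profiles,
         report = list(n_enterprises = length(unique(scores$enterprise_id)),
                       n_rows = nrow(scores), mean = unname(ds["mean"]),
                       sd = unname(ds["sd"]), band_sizes = band_sizes,
                       cutoffs = priorities$cutoffs)),
    class = "ehi_pipeline"
  )
}

#' @export
print.ehi_pipeline <- function(x, ...) {
  r <- x$report
  cat("EHI scoring pipeline\n")
  cat(sprintf("  %d enterprises, %d chemical rows, %d industries\n",
              r$n_enterprises, r$n_rows, nrow(x$industry_summary)))
  cat(sprintf("  industry statistic: mean %.2f, sd %.2f\n", r$mean, r$sd))
  cat(sprintf("  priority cutoffs: %.2f / %.2f / %.2f; band sizes %s\n",
              r$cutoffs["p90"], r$cutoffs["p70"], r$cutoffs["p50"],
              paste(r$band_sizes, collapse = "/")))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `enterprise_scores.csv` (per-chemical indices plus enterprise
#' totals), `industry_summary.csv` and `priorities.csv` (band table, with
#' the cutoffs echoed in a header comment line).
#'
#' @param pipeline An `ehi_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, dir) {
  if (!inherits(pipeline, "ehi_pipeline")) {
    stop("'pipeline' must come from run_pipeline()", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- as.data.frame(pipeline$scores)
  sc <- sc[, c("enterprise_id", "industry_code", "chemical_name", "ti", "ei",
               "mi", "pi", "pdi", "ehi", "ehi_total")]
  num <- vapply(sc, is.numeric, logical(1))
  sc[num] <- lapply(sc[num], round, 2)
  utils::write.csv(sc, file.path(dir, "enterprise_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pipeline$industry_summary),
                   file.path(dir, "industry_summary.csv"), row.names = FALSE)
  pr <- pipeline$priorities
  con <- file(file.path(dir, "priorities.csv"), "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoffs: p90=%.4f p70=%.4f p50=%.4f",
                     pr$cutoffs["p90"], pr$cutoffs["p70"], pr$cutoffs["p50"]),
             con)
  utils::write.csv(pr$bands[, c("industry_code", "industry_name",
                                "n_enterprises", "statistic", "band")],
                   con, row.names = FALSE)
  invisible(dir)
}
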