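# Built-in reference tables from the expert-elicitation survey (seven
# enterprises, nine chemicals, 20 senior industrial hygienists) and from the
# national application to 25 manufacturing industries.  These printed tables
# are the calibration inputs of the corrected EHI model.

#' Expert-panel rating tables for the four EHI component indices
#'
#' Mean and standard deviation of the ratings given by a panel of 20 senior
#' industrial hygiene inspectors to the toxicity (TI), exposure (EI),
#' management (MI) and protection (PI) indices over the conditions observed
#' in seven surveyed enterprises (nine chemicals with OEL-TWAs from 0.005 to
#' 750 ppm; exposure durations 10 to 250 min; 0 to 4 management measures;
#' all six engineering/PPE control combinations).  These tables are the
#' default calibration input of [ehi_calibration()].
#'
#' Each data frame carries the panel `mean` and `sd` plus the published
#' `corrected` rating for the same condition (for TI and EI the corrected
#' value is the published fit of the rating function evaluated at the
#' condition; for MI and PI it is the published corrected lookup).
#'
#' @return A named list of four data frames:
#' \describe{
#'   \item{ti}{`chemical`, `oel_twa` (ppm), `mean`, `sd`, `corrected`.}
#'   \item{ei}{`minutes`, `mean`, `sd`, `corrected` — ratings in \[0, 1\].}
#'   \item{mi}{`n_measures` (0–4), `mean`, `sd`, `corrected`.}
#'   \item{pi}{`engineering`, `ppe`, `mean`, `sd`, `corrected` — all six
#'     combinations.}
#' }
#' @examples
#' expert_ratings()$ei
#' @export
expert_ratings <- function() {
  list(
    ti = data.frame(
      chemical = c("toluene diisocyanate", "methylene bisphenyl isocyanate",
                   "N,N-dimethylformamide", "ethylene glycol",
                   "methylene chloride", "toluene", "methyl ethyl ketone",
                   "ethyl acetate", "acetone"),
      oel_twa = c(0.005, 0.02, 10, 50, 50, 100, 200, 400, 750),
      mean = c(86.31, 56.71, 10.23, 4.52, 4.52, 3.86, 3.09, 2.91, 2.30),
      sd = c(6.28, 4.34, 1.03, 0.67, 0.67, 0.37, 0.42, 0.42, 0.36),
      corrected = c(88.10, 58.04, 8.94, 5.51, 5.51, 4.47, 3.63, 2.94, 2.44),
      stringsAsFactors = FALSE
    ),
    ei = data.frame(
      minutes = c(10, 30, 40, 48, 75, 225, 250),
      mean = c(0.02, 0.07, 0.09, 0.12, 0.14, 0.53, 0.60),
      sd = c(0.01, 0.02, 0.05, 0.05, 0.08, 0.11, 0.13),
      corrected = c(0.02, 0.07, 0.10, 0.11, 0.18, 0.52, 0.58)
    ),
    mi = data.frame(
      n_measures = 0:4,
      mean = c(0.00, 0.38, 0.59, 0.82, 1.00),
      sd = c(0.00, 0.36, 0.06, 0.06, 0.00),
      corrected = c(0.18, 0.39, 0.60, 0.81, 1.00)
    ),
    pi = data.frame(
      engineering = c("EEn", "EEn", "EEp", "EEp", "EEe", "EEe"),
      ppe = c("PPEn", "PPEe", "PPEn", "PPEe", "PPEn", "PPEe"),
      mean = c(0.00, 0.18, 0.42, 0.61, 0.74, 1.00),
      sd = c(0.00, 0.06, 0.03, 0.12, 0.04, 0.00),
      corrected = c(0.00, 0.18, 0.42, 0.61, 0.74, 1.00),
      stringsAsFactors = FALSE
    )
  )
}

# Corrected (expert-system-derived) lookup ratings.  MI_cor and PI_cor are
# the published corrected columns; they are lookups, not re-fits, because
# the N = 0 row is corrected away from the panel mean (0.00 -> 0.18).
.mi_corrected <- c(`0` = 0.18, `1` = 0.39, `2` = 0.60, `3` = 0.81, `4` = 1.00)
.pi_corrected <- c("EEn+PPEn" = 0.00, "EEn+PPEe" = 0.18, "EEp+PPEn" = 0.42,
                   "EEp+PPEe" = 0.61, "EEe+PPEn" = 0.74, "EEe+PPEe" = 1.00)
.pi_original <- c("EEn+PPEn" = 0.00, "EEn+PPEe" = 0.20, "EEp+PPEn" = 0.30,
                  "EEp+PPEe" = 0.50, "EEe+PPEn" = 0.80, "EEe+PPEe" = 1.00)

#' Industry-level corrected EHI reference values from the national survey
#'
#' The 25 two-digit-SIC manufacturing industries covered by the 2006–2009
#' Taiwanese national occupational chemical hazard survey (702 enterprises in
#' total), with the published industry-level corrected EHI statistic (the
#' 95th percentile of the per-enterprise corrected EHI values within each
#' industry).  The survey databank itself was never deposited, so the
#' per-enterprise records cannot be redistributed; this table carries the
#' published industry aggregates only.  The two-digit `code` column is a
#' synthetic sequential placeholder — the original SIC codes were not
#' published.
#'
#' @return A data frame with columns `code`, `name`, `n_enterprises` and
#'   `ehi_p95` (25 rows; `sum(n_enterprises)` is 702).
#' @examples
#' head(industry_reference())
#' @export
industry_reference <- function() {
  x <- data.frame(
    name = c("Plastic products", "Petroleum products", "Metal products",
             "Transportation equipment", "Electrical equipment",
             "Electronic components", "Chemical materials", "Paper products",
             "Metalworking", "Chemical products", "Non-metallic mineral products",
             "Leather products", "Electronic products", "Wood products",
             "Printing and data storage products", "Drug manufacturing",
             "Textiles", "Foods", "Machinery and equipment", "Furniture",
             "Automotive", "Machinery and equipment maintenance",
             "Rubber products", "Beverages", "Clothing products"),
    n_enterprises = c(37L, 7L, 137L, 17L, 22L, 34L, 94L, 17L, 49L, 16L, 15L,
                      9L, 30L, 5L, 20L, 5L, 15L, 50L, 74L, 10L, 17L, 3L, 13L,
                      3L, 3L),
    ehi_p95 = c(43.47, 35.54, 33.17, 31.32, 27.23, 23.46, 21.66, 21.44,
                17.29, 14.06, 12.58, 12.03, 10.41, 10.16, 9.41, 8.94, 8.21,
                7.54, 5.71, 5.10, 2.48, 2.28, 1.33, 1.22, 0.82),
    stringsAsFactors = FALSE
  )
  data.frame(code = sprintf("%02d", seq_len(nrow(x))), x,
             stringsAsFactors = FALSE)
}

#' Default chemical palette for the synthetic survey generator
#'
#' The nine chemicals of the expert-elicitation survey with their OEL-TWAs,
#' plus two synthetic agents exercising the pragmatic OEL substitution
#' rules: a ceiling-only agent and a carcinogen without any OEL.
#'
#' @return A list of [chemical_agent()] objects.
#' @export
default_chemical_palette <- function() {
  ti <- expert_ratings()$ti
  pal <- mapply(function(nm, oel) chemical_agent(nm, oel_twa = oel),
                ti$chemical, ti$oel_twa, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  c(pal,
    list(chemical_agent("synthetic ceiling-only agent", oel_ceiling = 5),
         chemical_agent("synthetic no-OEL carcinogen",
                        no_oel_or_carcinogen = TRUE)))
}
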