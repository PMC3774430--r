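# Seeded generator of synthetic survey databanks with the structure of the
# 2006-2009 national program: 25 manufacturing industries with the surveyed
# per-industry enterprise counts (702 enterprises in total), per-enterprise
# chemical lists drawn from a palette spanning 0.001-1,000 ppm effective
# OELs, exposure durations over 10-480 min, 0-4 management measures and all
# engineering/PPE control combinations.  Entirely synthetic: it emulates
# the survey's structure, not the (undeposited) real databank's joint
# distributions.

.control_combos <- c("EEn+PPEn", "EEn+PPEe", "EEp+PPEn", "EEp+PPEe",
                     "EEe+PPEn", "EEe+PPEe")

check_probs <- function(p, what, n) {
  if (length(p) != n || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("'%s' must be %d non-negative probabilities summing to 1",
                 what, n), call. = FALSE)
  }
  p
}

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the national survey's published structure: the 25
#' industries with their surveyed enterprise counts, a chemical palette of
#' the nine expert-survey chemicals plus a ceiling-only and a no-OEL
#' synthetic agent, exposure durations drawn from a discrete mixture over
#' 10–480 min (covering both clamps of the corrected EI line), and 0–4
#' management measures.
#'
#' @param industries Data frame with `code`, `name`, `n_enterprises`
#'   (default: [industry_reference()]).
#' @param palette List of [chemical_agent()] objects (default:
#'   [default_chemical_palette()]).
#' @param n_chemicals_probs Probabilities of an enterprise using 1, 2, 3 or
#'   4 chemicals.
#' @param duration_pool,duration_probs Discrete exposure-duration mixture
#'   (minutes).
#' @param n_management_probs Probabilities of N = 0..4 management measures.
#' @param control_probs Probabilities of the six engineering/PPE
#'   combinations, in the order EEn+PPEn, EEn+PPEe, EEp+PPEn, EEp+PPEe,
#'   EEe+PPEn, EEe+PPEe.
#' @param seed Integer seed; every record derives from it deterministically.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(industries = industry_reference(),
                             palette = default_chemical_palette(),
                             n_chemicals_probs = c(0.4, 0.3, 0.2, 0.1),
                             duration_pool = c(10, 30, 40, 48, 75, 225, 250, 480),
                             duration_probs = c(0.15, 0.15, 0.10, 0.10,
                                                0.15, 0.15, 0.10, 0.10),
                             n_management_probs = c(0.10, 0.20, 0.30, 0.25, 0.15),
                             control_probs = c(0.10, 0.10, 0.20, 0.25,
                                               0.15, 0.20),
                             seed = 1L) {
  if (!all(c("code", "name", "n_enterprises") %in% names(industries)) ||
      nrow(industries) == 0L) {
    stop("'industries' needs columns code, name, n_enterprises", call. = FALSE)
  }
  if (any(industries$n_enterprises < 1)) {
    stop("each industry needs at least one enterprise", call. = FALSE)
  }
  if (!length(palette) || !all(vapply(palette, inherits, logical(1),
                                      "chemical_agent"))) {
    stop("'palette' must be a non-empty list of chemical_agent objects",
         call. = FALSE)
  }
  if (length(duration_pool) != length(duration_probs) ||
      any(duration_pool < 0)) {
    stop("'duration_pool' and 'duration_probs' must match and be non-negative",
         call. = FALSE)
  }
  check_probs(n_chemicals_probs, "n_chemicals_probs", length(n_chemicals_probs))
  check_probs(duration_probs, "duration_probs", length(duration_pool))
  check_probs(n_management_probs, "n_management_probs", 5L)
  check_probs(control_probs, "control_probs", 6L)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(
    list(industries = industries, palette = palette,
         n_chemicals_probs = n_chemicals_probs,
         duration_pool = duration_pool, duration_probs = duration_probs,
         n_management_probs = n_management_probs,
         control_probs = control_probs, seed = seed),
    class = "generator_config"
  )
}

agent_row <- function(agent, minutes) {
  data.frame(chemical_name = agent$name, cas = agent$cas,
             oel_twa_ppm = agent$oel_twa, oel_ceiling_ppm = agent$oel_ceiling,
             carcinogen_no_oel = as.integer(agent$no_oel_or_carcinogen),
             exposure_minutes = minutes, stringsAsFactors = FALSE)
}

# One RNG substream per enterprise, derived from (seed, global enterprise
# index): adding or reordering industries later does not perturb the draws
# of enterprises that keep their index.
enterprise_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 30269) %% 2147483629
}

generate_one <- function(cfg, code, name, ent_index, chem_weights,
                         duration_probs, n_management_probs, control_probs) {
  set.seed(enterprise_seed(cfg$seed, ent_index))
  n_chem <- sample.int(length(cfg$n_chemicals_probs), 1,
                       prob = cfg$n_chemicals_probs)
  n_chem <- min(n_chem, length(cfg$palette))
  picks <- sample.int(length(cfg$palette), n_chem, replace = FALSE,
                      prob = chem_weights)
  minutes <- cfg$duration_pool[sample.int(length(cfg$duration_pool), n_chem,
                                          replace = TRUE,
                                          prob = duration_probs)]
  n_mgmt <- sample(0:4, 1, prob = n_management_probs)
  combo <- sample(.control_combos, 1, prob = control_probs)
  ee_ppe <- strsplit(combo, "+", fixed = TRUE)[[1]]
  rows <- do.call(rbind, Map(function(i, m) agent_row(cfg$palette[[i]], m),
                             picks, minutes))
  data.frame(enterprise_id = sprintf("E%04d", ent_index),
             industry_code = code, industry_name = name,
             rows,
             n_management = n_mgmt,
             engineering_control = ee_ppe[1], ppe = ee_ppe[2],
             stringsAsFactors = FALSE, row.names = NULL)
}

generate_impl <- function(cfg, risk_of = function(code) 0, effect = 0) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # risk-shifted mixtures used at effect > 0 for high-risk industries
  risky_duration <- local({
    w <- cfg$duration_pool / sum(cfg$duration_pool)
    w / sum(w)
  })
  risky_mgmt <- c(0.40, 0.30, 0.15, 0.10, 0.05)
  risky_control <- c(0.35, 0.25, 0.15, 0.10, 0.10, 0.05)
  base_chem <- rep(1 / length(cfg$palette), length(cfg$palette))
  tox <- vapply(cfg$palette, function(a) 2^(-log10(effective_oel(a))),
                numeric(1))
  risky_chem <- tox / sum(tox)

  mix <- function(base, risky, e) (1 - e) * base + e * risky

  ind <- cfg$industries
  ent_index <- 0L
  out <- vector("list", sum(ind$n_enterprises))
  k <- 0L
  for (i in seq_len(nrow(ind))) {
    e <- effect * risk_of(ind$code[i])
    for (j in seq_len(ind$n_enterprises[i])) {
      ent_index <- ent_index + 1L
      k <- k + 1L
      out[[k]] <- generate_one(
        cfg, ind$code[i], ind$name[i], ent_index,
        chem_weights = mix(base_chem, risky_chem, e),
        duration_probs = mix(cfg$duration_probs, risky_duration, e),
        n_management_probs = mix(cfg$n_management_probs, risky_mgmt, e),
        control_probs = mix(cfg$control_probs, risky_control, e))
    }
  }
  as_survey(do.call(rbind, out), strict = TRUE,
            source = sprintf("synthetic(seed=%d)", cfg$seed))
}

#' Generate a synthetic survey databank
#'
#' Deterministic for a fixed seed; enterprise counts per industry are
#' exactly as configured, and every generated row passes strict survey
#' validation.
#'
#' @param config A [generator_config()].
#' @return An `ehi_survey` data frame.
#' @examples
#' survey <- generate_survey(generator_config(seed = 42,
#'   industries = industry_reference()[1:4, ]))
#' nrow(survey)
#' @export
generate_survey <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("'config' must come from generator_config()", call. = FALSE)
  }
  generate_impl(config)
}

#' Generate a tiered synthetic survey with designated high-risk industries
#'
#' Industries listed in `high_risk_codes` draw longer exposure durations,
#' fewer management measures, weaker engineering/PPE controls and
#' lower-OEL (more toxic) chemicals, with strength `effect`; the remaining
#' industries follow the base configuration.  Used for recovery tests: the
#' priority banding should place the high-risk industries in bands 1–2.
#'
#' @param config A [generator_config()].
#' @param high_risk_codes Character vector of industry codes to shift.
#' @param effect Shift strength in \[0, 1\]; 0 reduces to
#'   [generate_survey()].
#' @return An `ehi_survey` data frame.
#' @export
generate_survey_tiered <- function(config, high_risk_codes, effect = 1) {
  if (!inherits(config, "generator_config")) {
    stop("'config' must come from generator_config()", call. = FALSE)
  }
  if (effect < 0 || effect > 1) stop("'effect' must lie in [0, 1]",
                                     call. = FALSE)
  unknown <- setdiff(high_risk_codes, config$industries$code)
  if (length(unknown)) {
    stop("unknown industry code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  generate_impl(config,
                risk_of = function(code) as.numeric(code %in% high_risk_codes),
                effect = effect)
}
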