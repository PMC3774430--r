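#' Describe a chemical agent by its occupational exposure limits
#'
#' A chemical enters the Exposure Hazard Index through a single effective
#' 8-hour time-weighted-average occupational exposure limit (OEL-TWA, in
#' ppm).  Agents that only carry a ceiling limit, and carcinogens or new
#' chemicals without any OEL, are handled by the pragmatic substitution
#' rules of [effective_oel()].
#'
#' @param name Chemical name (required, non-empty).
#' @param oel_twa OEL-TWA in ppm, or `NA` when the agent has none.
#' @param oel_ceiling OEL-Ceiling in ppm, or `NA`.
#' @param no_oel_or_carcinogen `TRUE` for a carcinogen or a chemical with no
#'   OEL of any kind; such agents are rated like the most toxic listed
#'   chemical (effective OEL 0.001 ppm).
#' @param cas Optional CAS registry number (free text).
#'
#' @return An object of class `chemical_agent`.
#' @examples
#' chemical_agent("toluene", oel_twa = 100)
#' chemical_agent("formaldehyde-like", oel_ceiling = 0.3)
#' chemical_agent("novel carcinogen", no_oel_or_carcinogen = TRUE)
#' @export
chemical_agent <- function(name, oel_twa = NA_real_, oel_ceiling = NA_real_,
                           no_oel_or_carcinogen = FALSE, cas = NA_character_) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop("'name' must be a single non-empty string", call. = FALSE)
  }
  oel_twa <- as.numeric(oel_twa)
  oel_ceiling <- as.numeric(oel_ceiling)
  for (v in list(oel_twa = oel_twa, oel_ceiling = oel_ceiling)) {
    if (!is.na(v) && (!is.finite(v) || v <= 0)) {
      stop(sprintf("agent '%s': OEL values must be positive and finite", name),
           call. = FALSE)
    }
  }
  if (!isTRUE(no_oel_or_carcinogen) && !isFALSE(no_oel_or_carcinogen)) {
    stop("'no_oel_or_carcinogen' must be TRUE or FALSE", call. = FALSE)
  }
  if (is.na(oel_twa) && is.na(oel_ceiling) && !no_oel_or_carcinogen) {
    stop(sprintf(paste0("agent '%s' has no OEL-TWA and no OEL-Ceiling; set ",
                        "no_oel_or_carcinogen = TRUE for such chemicals"), name),
         call. = FALSE)
  }
  structure(
    list(name = name, cas = cas, oel_twa = oel_twa, oel_ceiling = oel_ceiling,
         no_oel_or_carcinogen = no_oel_or_carcinogen),
    class = "chemical_agent"
  )
}

#' @export
print.chemical_agent <- function(x, ...) {
  lim <- if (!is.na(x$oel_twa)) {
    sprintf("OEL-TWA %g ppm", x$oel_twa)
  } else if (!is.na(x$oel_ceiling)) {
    sprintf("OEL-Ceiling %g ppm", x$oel_ceiling)
  } else {
    "no OEL (carcinogen/new chemical)"
  }
  cat(sprintf("<chemical_agent> %s [%s]\n", x$name, lim))
  invisible(x)
}

#' Effective OEL-TWA of a chemical agent
#'
#' Reduces an agent's limit information to the single OEL-TWA (ppm) the
#' toxicity index is rated on: the OEL-TWA itself when present; three times
#' the OEL-Ceiling for ceiling-only agents; and 0.001 ppm (the lowest listed
#' OEL-TWA) for carcinogens and chemicals without any OEL.
#'
#' @param agent A [chemical_agent()].
#' @return Effective OEL-TWA in ppm (positive scalar).
#' @examples
#' effective_oel(chemical_agent("acetone", oel_twa = 750))        # 750
#' effective_oel(chemical_agent("ceiling-only", oel_ceiling = 10)) # 30
#' @export
effective_oel <- function(agent) {
  if (!inherits(agent, "chemical_agent")) {
    stop("'agent' must be a chemical_agent", call. = FALSE)
  }
  if (!is.na(agent$oel_twa)) return(agent$oel_twa)
  if (!is.na(agent$oel_ceiling)) return(3 * agent$oel_ceiling)
  if (isTRUE(agent$no_oel_or_carcinogen)) return(0.001)
  stop(sprintf("agent '%s' carries no usable OEL information", agent$name),
       call. = FALSE)
}

# Canonical spellings of the control enums; used by validators everywhere.
.engineering_levels <- c("EEe", "EEp", "EEn")
.ppe_levels <- c("PPEe", "PPEn")

check_engineering <- function(x) {
  if (length(x) != 1L || !(x %in% .engineering_levels)) {
    stop(sprintf("engineering control must be one of %s",
                 paste(.engineering_levels, collapse = ", ")), call. = FALSE)
  }
  x
}

check_ppe <- function(x) {
  if (length(x) != 1L || !(x %in% .ppe_levels)) {
    stop(sprintf("ppe must be one of %s", paste(.ppe_levels, collapse = ", ")),
         call. = FALSE)
  }
  x
}

check_n_measures <- function(n) {
  if (length(n) != 1L || is.na(n) || n %% 1 != 0 || n < 0 || n > 4) {
    stop("number of management measures must be an integer between 0 and 4",
         call. = FALSE)
  }
  as.integer(n)
}

check_minutes <- function(minutes) {
  if (length(minutes) != 1L || !is.finite(minutes) || minutes < 0) {
    stop("exposure duration must be a finite non-negative number of minutes",
         call. = FALSE)
  }
  as.numeric(minutes)
}
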