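# Shared fixture builders: tiny surveys constructed in code.

survey_row <- function(enterprise_id = "E1", industry_code = "01",
                       industry_name = "Plastic products",
                       chemical_name = "DMF", oel_twa_ppm = 10,
                       oel_ceiling_ppm = NA_real_, carcinogen_no_oel = 0L,
                       exposure_minutes = 225, n_management = 2L,
                       engineering_control = "EEp", ppe = "PPEe",
                       cas = NA_character_) {
  data.frame(enterprise_id = enterprise_id, industry_code = industry_code,
             industry_name = industry_name, chemical_name = chemical_name,
             cas = cas, oel_twa_ppm = oel_twa_ppm,
             oel_ceiling_ppm = oel_ceiling_ppm,
             carcinogen_no_oel = carcinogen_no_oel,
             exposure_minutes = exposure_minutes, n_management = n_management,
             engineering_control = engineering_control, ppe = ppe,
             stringsAsFactors = FALSE)
}

# a survey of n single-chemical enterprises with chosen per-enterprise EHIs
# realized through exposure minutes (corrected scheme, all else fixed)
tiny_survey <- function(minutes, industry_code = "01",
                        industry_name = "Plastic products") {
  do.call(rbind, lapply(seq_along(minutes), function(i) {
    survey_row(enterprise_id = sprintf("E%03d", i),
               industry_code = industry_code, industry_name = industry_name,
               exposure_minutes = minutes[i])
  }))
}

# closed-form type-7 percentile oracle, independent of stats::quantile
percentile_oracle <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

table3_values <- function() industry_reference()$ehi_p95
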