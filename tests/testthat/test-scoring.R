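test_that("a single-chemical enterprise scores the closed-form product", {
  # TI = 8.94, EI = 0.52, MI = 0.60, PI = 0.42 -> PDI = 0.49, EHI = 2.278
  cal <- ehi_calibration()
  cal$k0 <- 8.94   # pin TI at 1 ppm for the closed-form check
  cal$ei_slope <- 0; cal$ei_intercept <- 0.52
  es <- score_enterprise(
    data.frame(chemical_name = "X", oel_twa_ppm = 1, oel_ceiling_ppm = NA,
               carcinogen_no_oel = 0, exposure_minutes = 100),
    n_management = 2, engineering = "EEp", ppe = "PPEn", params = cal)
  expect_equal(es$indices$mi, 0.60)
  expect_equal(es$indices$pi, 0.42)
  expect_equal(es$ehi_total, 8.94 * 0.52 * 0.49, tolerance = 0.001 / 2.278)
})

test_that("enterprise EHI is additive over chemicals", {
  exp1 <- data.frame(chemical_name = c("DMF", "toluene"),
                     oel_twa_ppm = c(10, 100), oel_ceiling_ppm = NA,
                     carcinogen_no_oel = 0, exposure_minutes = c(225, 48))
  one <- score_enterprise(exp1, 2, "EEp", "PPEe", enterprise_id = "A")
  expect_equal(one$ehi_total, sum(one$indices$ehi))
  # duplicating a chemical row doubles its contribution exactly
  dup <- score_enterprise(rbind(exp1, exp1[1, ]), 2, "EEp", "PPEe")
  expect_equal(dup$ehi_total, one$ehi_total + one$indices$ehi[1])
  # empty exposure list scores zero
  expect_equal(score_enterprise(data.frame(), 2, "EEp", "PPEe")$ehi_total, 0)
})

test_that("full protection yields zero EHI regardless of chemicals", {
  exposures <- data.frame(chemical_name = c("TDI", "carc"),
                          oel_twa_ppm = c(0.005, NA), oel_ceiling_ppm = NA,
                          carcinogen_no_oel = c(0, 1),
                          exposure_minutes = c(480, 480))
  es <- score_enterprise(exposures, 4, "EEe", "PPEe")
  expect_equal(es$ehi_total, 0)
})

test_that("scoring errors name the enterprise", {
  bad <- data.frame(chemical_name = "X", oel_twa_ppm = NA,
                    oel_ceiling_ppm = NA, carcinogen_no_oel = 0,
                    exposure_minutes = 100)
  expect_error(score_enterprise(bad, 2, "EEp", "PPEe",
                                enterprise_id = "E077"), "E077")
})

test_that("percentile matches the interpolation oracle and its edge cases", {
  expect_equal(ehi_percentile(1:5, 0.95), 4.8)
  set.seed(51)
  for (rep in 1:1000) {
    n <- sample(2:50, 1)
    v <- stats::rlnorm(n, 1, 1)
    p <- runif(1)
    expect_equal(ehi_percentile(v, p), percentile_oracle(v, p),
                 tolerance = 1e-9)
  }
  v <- stats::rlnorm(20)
  expect_equal(ehi_percentile(v, 0), min(v))
  expect_equal(ehi_percentile(v, 1), max(v))
  expect_error(ehi_percentile(numeric(0), 0.5), "non-empty")
  expect_error(ehi_percentile(1:5, 1.2), "\\[0, 1\\]")
})

test_that("the published 25 industry values give the published cutoffs", {
  v <- table3_values()
  expect_equal(round(ehi_percentile(v, 0.9), 2), 32.43)
  expect_equal(round(ehi_percentile(v, 0.7), 2), 20.61)
  expect_equal(round(ehi_percentile(v, 0.5), 2), 10.41)
  expect_equal(round(unname(distribution_stats(v)), 1), c(14.7, 12.0))
})

test_that("distribution_stats uses the sample standard deviation", {
  expect_equal(unname(distribution_stats(c(0, 2))), c(1, sqrt(2)))
  expect_equal(unname(distribution_stats(rep(3, 5))["sd"]), 0)
  expect_error(distribution_stats(1), "at least two")
})

test_that("industry summaries group, count and reduce correctly", {
  sv <- rbind(tiny_survey(c(48, 75, 225, 250, 480), "01", "Plastics"),
              tiny_survey(120, "02", "Foods"))
  sv$enterprise_id <- paste0(sv$industry_code, sv$enterprise_id)
  scores <- score_survey(sv)
  sm <- summarize_industries(scores)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n_enterprises[order(sm$industry_code)], c(5L, 1L))
  one <- sm$statistic[sm$industry_code == "02"]
  expect_equal(one, scores$ehi_total[scores$industry_code == "02"][1])
  ehis <- sort(unique(scores$ehi_total[scores$industry_code == "01"]))
  expect_equal(sm$statistic[sm$industry_code == "01"],
               percentile_oracle(ehis, 0.95))
  # configured mean statistic
  sm2 <- summarize_industries(scores, statistic = "mean")
  expect_equal(sm2$statistic[sm2$industry_code == "01"], mean(ehis))
})

test_that("priority banding uses inclusive lower bounds and partitions", {
  v <- table3_values()
  sm <- data.frame(industry_code = sprintf("%02d", seq_along(v)),
                   industry_name = "x", n_enterprises = 1L, statistic = v)
  pr <- assign_priorities(sm)
  sizes <- as.integer(table(factor(pr$bands$band, levels = 1:4)))
  expect_equal(sizes, c(3L, 5L, 5L, 12L))
  expect_equal(sum(sizes), nrow(sm))
  # a value exactly at a cutoff lands in the higher band
  expect_equal(pr$bands$band[pr$bands$statistic == 10.41], 3L)
  # all-equal statistics: everything is in band 1
  tied <- within(sm, statistic <- 5)
  expect_true(all(assign_priorities(tied)$bands$band == 1L))
  expect_error(assign_priorities(sm[0, ]), "no industries")
  expect_warning(assign_priorities(sm[1:3, ]), "fewer than 4")
})

test_that("scaling all scores scales cutoffs but not band membership", {
  v <- table3_values()
  sm <- data.frame(industry_code = sprintf("%02d", seq_along(v)),
                   industry_name = "x", n_enterprises = 1L, statistic = v)
  a <- assign_priorities(sm)
  b <- assign_priorities(within(sm, statistic <- statistic * 3.7))
  expect_equal(b$cutoffs, a$cutoffs * 3.7)
  expect_equal(b$bands$band, a$bands$band)
})

test_that("pipeline results are invariant to record order", {
  cfg <- generator_config(seed = 9,
                          industries = industry_reference()[1:8, ])
  sv <- generate_survey(cfg)
  p1 <- run_pipeline(sv)
  set.seed(1); perm <- sample(nrow(sv))
  sv2 <- as_survey(as.data.frame(sv)[perm, ], strict = TRUE)
  p2 <- run_pipeline(sv2)
  expect_equal(p2$industry_summary, p1$industry_summary)
  expect_equal(p2$priorities$cutoffs, p1$priorities$cutoffs)
  expect_equal(p2$priorities$bands$band[order(p2$priorities$bands$industry_code)],
               p1$priorities$bands$band[order(p1$priorities$bands$industry_code)])
  s1 <- as.data.frame(p1$scores); s2 <- as.data.frame(p2$scores)
  key <- function(d) d[order(d$enterprise_id, d$chemical_name,
                             d$exposure_minutes), c("ehi", "ehi_total")]
  expect_equal(key(s2), key(s1), ignore_attr = TRUE)
})

test_that("band index profiles report mean, SE and the generated ordering", {
  # two identical enterprises -> SE 0; single value -> SE 0
  sv <- tiny_survey(c(225, 225))
  scores <- score_survey(sv)
  sm <- summarize_industries(scores)
  pr <- suppressWarnings(assign_priorities(sm))
  prof <- suppressWarnings(band_index_profiles(scores, pr))
  expect_equal(unique(prof$se), 0)
  expect_equal(prof$mean[prof$index == "ei"], rate_ei(225, "corrected"))
  expect_equal(prof$lower, prof$mean - 1.96 * prof$se)
  # tiered generator: band-1 EI mean exceeds band-4 EI mean
  ind <- industry_reference()[, c("code", "name")]
  ind$n_enterprises <- 8L
  hr <- c("03", "07", "12", "18", "22")
  svt <- generate_survey_tiered(generator_config(industries = ind, seed = 5),
                                high_risk_codes = hr)
  pt <- run_pipeline(svt)
  prof_t <- pt$profiles
  ei1 <- prof_t$mean[prof_t$band == 1 & prof_t$index == "ei"]
  ei4 <- prof_t$mean[prof_t$band == 4 & prof_t$index == "ei"]
  expect_gt(ei1, ei4)
})
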