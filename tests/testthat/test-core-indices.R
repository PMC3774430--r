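test_that("chemical agents validate their OEL information", {
  expect_s3_class(chemical_agent("toluene", oel_twa = 100), "chemical_agent")
  expect_error(chemical_agent("orphan"), "no_oel_or_carcinogen")
  expect_error(chemical_agent("neg", oel_twa = -1), "positive")
  expect_error(chemical_agent("zero", oel_ceiling = 0), "positive")
  expect_error(chemical_agent(""), "non-empty")
})

test_that("effective OEL applies the TWA, 3x-ceiling and carcinogen rules", {
  expect_identical(effective_oel(chemical_agent("a", oel_twa = 50)), 50)
  expect_identical(effective_oel(chemical_agent("b", oel_ceiling = 10)), 30)
  expect_identical(
    effective_oel(chemical_agent("c", no_oel_or_carcinogen = TRUE)), 0.001)
  # TWA wins when both limits are present
  expect_identical(
    effective_oel(chemical_agent("d", oel_twa = 5, oel_ceiling = 10)), 5)
})

test_that("original TI reproduces the eight-level band table", {
  cases <- list(list(0.005, 64), list(10, 8), list(50, 4), list(100, 4),
                list(200, 2), list(750, 2), list(0.001, 128), list(1500, 1))
  for (cs in cases) {
    expect_equal(rate_ti(chemical_agent("x", oel_twa = cs[[1]]), "original"),
                 cs[[2]], info = sprintf("OEL %g", cs[[1]]))
  }
  # band edges: lower bound exclusive, upper inclusive
  expect_equal(rate_ti(10, "original"), 8)
  expect_equal(rate_ti(10.0001, "original"), 4)
  expect_equal(rate_ti(chemical_agent("carc", no_oel_or_carcinogen = TRUE),
                       "original"), 128)
})

test_that("original TI band assignment matches a scan-all-rows oracle", {
  # oracle scans the printed band table row by row
  bands <- data.frame(lo = c(1000, 100, 10, 1, 0.1, 0.01, 0.001, 0),
                      hi = c(Inf, 1000, 100, 10, 1, 0.1, 0.01, 0.001),
                      ti = c(1, 2, 4, 8, 16, 32, 64, 128))
  oracle <- function(oel) {
    for (i in seq_len(nrow(bands))) {
      if (oel > bands$lo[i] && oel <= bands$hi[i]) return(bands$ti[i])
    }
    128
  }
  set.seed(11)
  oels <- c(10^runif(10000, -4, 4), bands$hi[-1], bands$lo[-8])
  expect_equal(rate_ti(oels, "original"),
               vapply(oels, oracle, numeric(1)))
})

test_that("corrected TI follows the fitted power law and its halving law", {
  expect_equal(rate_ti(chemical_agent("DMF", oel_twa = 10), "corrected"),
               8.94, tolerance = 0.02 / 8.94)
  cal <- ehi_calibration()
  expect_equal(rate_ti(1, "corrected", cal), cal$k0)
  set.seed(21)
  x <- 10^runif(50, -3, 3)
  expect_equal(rate_ti(10 * x, "corrected", cal),
               rate_ti(x, "corrected", cal) / 2, tolerance = 1e-9)
  # published pair: TI(10 ppm) is exactly twice TI(100 ppm)
  expect_equal(rate_ti(10, "corrected", cal) / rate_ti(100, "corrected", cal),
               2, tolerance = 1e-12)
  # carcinogen handling: extrapolated by default, pinnable at 128
  carc <- chemical_agent("carc", no_oel_or_carcinogen = TRUE)
  expect_equal(rate_ti(carc, "corrected", cal), cal$k0 * 8, tolerance = 1e-12)
  pin <- ehi_calibration(carcinogen_ti = "pin")
  expect_equal(rate_ti(carc, "corrected", pin), 128)
})

test_that("TI is monotone non-increasing in the effective OEL", {
  oels <- sort(10^runif(200, -4, 4))
  for (scheme in c("original", "corrected")) {
    ti <- rate_ti(oels, scheme)
    expect_true(all(diff(ti) <= 1e-12), info = scheme)
  }
  expect_error(rate_ti(-1, "original"), "positive")
  expect_error(rate_ti(0, "corrected"), "positive")
})

test_that("EI rates duration bands originally and a clamped line corrected", {
  expect_equal(rate_ei(c(10, 119, 120, 225, 239, 240, 480), "original"),
               c(0.30, 0.30, 0.60, 0.60, 0.60, 1.00, 1.00))
  expect_equal(rate_ei(48, "corrected"), 0.11, tolerance = 0.015 / 0.11)
  expect_equal(rate_ei(600, "corrected"), 1)   # upper clamp
  expect_equal(rate_ei(0, "corrected"), 0)     # lower clamp (negative fit)
  # monotone non-decreasing, bounded
  m <- sort(runif(100, 0, 600))
  for (scheme in c("original", "corrected")) {
    ei <- rate_ei(m, scheme)
    expect_true(all(diff(ei) >= -1e-12) && all(ei >= 0) && all(ei <= 1),
                info = scheme)
  }
  expect_error(rate_ei(-5, "original"), "non-negative")
})

test_that("MI rates the management-measure count in both schemes", {
  expect_equal(rate_mi(0:4, "original"), c(0, 0.25, 0.50, 0.75, 1.00))
  expect_equal(rate_mi(0:4, "corrected"), c(0.18, 0.39, 0.60, 0.81, 1.00))
  expect_true(all(diff(rate_mi(0:4, "corrected")) > 0))
  expect_error(rate_mi(5, "original"), "between 0 and 4")
  expect_error(rate_mi(2.5, "corrected"), "between 0 and 4")
})

test_that("PI rates the six control combinations in both schemes", {
  combos <- expand.grid(ee = c("EEn", "EEp", "EEe"), ppe = c("PPEn", "PPEe"),
                        stringsAsFactors = FALSE)
  orig <- rate_pi(combos$ee, combos$ppe, "original")
  corr <- rate_pi(combos$ee, combos$ppe, "corrected")
  expect_equal(rate_pi("EEn", "PPEn", "original"), 0)
  expect_equal(rate_pi("EEe", "PPEn", "original"), 0.80)
  expect_equal(rate_pi("EEp", "PPEe", "corrected"), 0.61)
  expect_equal(rate_pi("EEn", "PPEn", "corrected"), 0)
  # ordering EEn < EEp < EEe within each PPE level, and PPEn < PPEe
  for (ratings in list(orig, corr)) {
    byppe <- split(ratings, combos$ppe)
    for (v in byppe) expect_true(all(diff(v) > 0))
    expect_true(all(ratings[combos$ppe == "PPEe"] >
                      ratings[combos$ppe == "PPEn"]))
  }
  expect_error(rate_pi("EE?", "PPEe", "original"), "engineering")
  expect_error(rate_pi("EEe", "none", "corrected"), "ppe")
})

test_that("PDI is a decreasing, bounded deficiency under every formula", {
  expect_equal(compute_pdi(1, 1), 0)
  expect_equal(compute_pdi(0, 0), 1)
  expect_equal(compute_pdi(0.60, 0.42), 0.49)
  expect_equal(compute_pdi(0.60, 0.42, "product_complement"), 0.4 * 0.58)
  expect_equal(compute_pdi(0.60, 0.42, "sum_complement"), 0.98)
  set.seed(31)
  mi <- runif(200); pi <- runif(200); d <- runif(200, 0, 0.2)
  for (f in c("average", "product_complement", "sum_complement")) {
    base <- compute_pdi(mi, pi, f)
    expect_true(all(compute_pdi(pmin(1, mi + d), pi, f) <= base + 1e-12),
                info = f)
    expect_true(all(compute_pdi(mi, pmin(1, pi + d), f) <= base + 1e-12),
                info = f)
  }
  # affine symmetry of the default formula
  expect_equal(compute_pdi(mi, pi) + compute_pdi(1 - mi, 1 - pi),
               rep(1, 200))
  expect_true(all(compute_pdi(mi, pi) >= 0 & compute_pdi(mi, pi) <= 1))
  expect_error(compute_pdi(1.2, 0.5), "\\[0, 1\\]")
})
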