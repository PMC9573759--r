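# Frozen expected values were computed by independent hand arithmetic on the
# printed equations (evaluating each linear predictor / power law term by
# term), not by calling the package.

test_that("unit conversions match their molar-mass definitions", {
  expect_equal(cr_mmol_to_mg(0), 0)
  expect_equal(cr_mmol_to_mg(1), 113.12)
  expect_equal(cr_mmol_to_mg(8.93), 1010.1616)
  expect_error(cr_mmol_to_mg(-1), "cr")

  expect_equal(na_mmol_to_g_salt(0), 0)
  expect_equal(round(na_mmol_to_g_salt(12.30), 2), 0.72)
  expect_equal(round(na_mmol_to_g_salt(17.1), 2), 1.00)
  expect_error(na_mmol_to_g_salt(-0.1), "na")

  # round trip to 1e-12 relative
  x <- c(0.3, 8.93, 120)
  expect_equal(cr_mmol_to_mg(x) / 113.12, x, tolerance = 1e-12)
})

test_that("new-formula sodium and potassium estimates match hand evaluation", {
  expect_equal(estimate_na_new("male", 65, 25, 130, 8.9), 193.0461573,
               tolerance = 1e-8)
  expect_equal(estimate_na_new("female", 65, 25, 130, 8.9), 164.1919775,
               tolerance = 1e-8)
  expect_equal(estimate_k_new("male", 65, 25, 55, 130, 8.9), 52.6291558,
               tolerance = 1e-7)
  expect_equal(estimate_k_new("female", 65, 25, 55, 130, 8.9), 39.9197427,
               tolerance = 1e-7)
  # intercept-only limit: all covariates at zero contribution
  b <- equation_registry()
  expect_equal(suppressWarnings(
    estimate_na_new("male", 1e-12, 1e-12, 0, 1)), 41.492, tolerance = 1e-6)
  # both log ratios vanish at k = cr, na = cr:
  # -0.052*65 + 0.410*25 + 0.031*55 - 1.035 = 7.54 by hand
  expect_equal(estimate_k_new("male", 65, 25, 55, 55, 55), 7.54,
               tolerance = 1e-10)
  expect_error(estimate_k_new("male", 65, 25, 0, 130, 8.9), "spot_k")
  expect_error(estimate_na_new("male", 65, 25, 130, 0), "spot_cr")
})

test_that("predicted 24 h creatinine matches hand arithmetic and guards its domain", {
  expect_equal(predict_creatinine_kawasaki("male", 70, 165, 65), 1376.9)
  expect_equal(predict_creatinine_kawasaki("female", 70, 165, 65), 1059.15)
  expect_equal(predict_creatinine_tanaka(70, 165, 65), 1328.35)
  expect_equal(predict_creatinine_tanaka(60, 150, 80), 906.75)
  # intercept-only limits are negative: out of domain
  expect_error(predict_creatinine_kawasaki("male", 1e-6, 1e-6, 1e-6),
               "domain")
  expect_error(predict_creatinine_tanaka(1e-6, 1e-6, 1e-6), "domain")
})

test_that("Kawasaki, Tanaka and INTERSALT estimates match hand evaluation", {
  expect_equal(estimate_kawasaki("male", 70, 165, 65, 130, 8.9, "na"),
               217.3430609, tolerance = 1e-7)
  expect_equal(estimate_kawasaki("male", 70, 165, 65, 55, 8.9, "k"),
               62.4453839, tolerance = 1e-7)
  expect_equal(estimate_tanaka(70, 165, 65, 130, 8.9, "na"),
               165.1519341, tolerance = 1e-7)
  expect_equal(estimate_tanaka(70, 165, 65, 55, 8.9, "k"),
               48.1086554, tolerance = 1e-7)
  expect_equal(estimate_kawasaki("male", 70, 165, 65, 0, 8.9, "na"), 0)
  expect_equal(estimate_tanaka(70, 165, 65, 0, 8.9, "k"), 0)
  expect_equal(estimate_na_intersalt("male", 65, 25, 130, 55, 8.9), 173.035)
  expect_equal(estimate_na_intersalt("female", 65, 25, 130, 55, 8.9), 110.846)
  # male intercept-only limit
  expect_equal(suppressWarnings(
    estimate_na_intersalt("male", 1e-12, 1e-12, 0, 0, 0)), 25.46,
    tolerance = 1e-6)
})

test_that("power-law scaling: doubling spot Na scales Kawasaki by sqrt(2), Tanaka by 2^0.392", {
  base_k <- estimate_kawasaki("male", 70, 165, 65, 130, 8.9, "na")
  dbl_k <- estimate_kawasaki("male", 70, 165, 65, 260, 8.9, "na")
  expect_equal(dbl_k / base_k, sqrt(2), tolerance = 1e-9)
  base_t <- estimate_tanaka(70, 165, 65, 130, 8.9, "na")
  dbl_t <- estimate_tanaka(70, 165, 65, 260, 8.9, "na")
  expect_equal(dbl_t / base_t, 2^0.392, tolerance = 1e-9)
})

test_that("every sodium estimate increases in spot Na; new K estimate decreases in spot Na", {
  na_grid <- seq(20, 300, by = 20)
  for (fn in list(
    function(na) estimate_na_new("female", 65, 25, na, 8.9),
    function(na) estimate_kawasaki("male", 70, 165, 65, na, 8.9, "na"),
    function(na) estimate_tanaka(70, 165, 65, na, 8.9, "na"),
    function(na) estimate_na_intersalt("male", 65, 25, na, 55, 8.9))) {
    vals <- vapply(na_grid, fn, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
  k_vals <- vapply(na_grid, function(na)
    estimate_k_new("male", 65, 25, 55, na, 8.9), numeric(1))
  expect_true(all(diff(k_vals) < 0))
})

test_that("sex dispatch: sex-specific formulas differ between sexes, Tanaka does not have one", {
  expect_false(estimate_na_new("male", 65, 25, 130, 8.9) ==
                 estimate_na_new("female", 65, 25, 130, 8.9))
  expect_false(estimate_k_new("male", 65, 25, 55, 130, 8.9) ==
                 estimate_k_new("female", 65, 25, 55, 130, 8.9))
  expect_false(predict_creatinine_kawasaki("male", 70, 165, 65) ==
                 predict_creatinine_kawasaki("female", 70, 165, 65))
  expect_false(estimate_na_intersalt("male", 65, 25, 130, 55, 8.9) ==
                 estimate_na_intersalt("female", 65, 25, 130, 55, 8.9))
})

test_that("the registry agrees with an independently keyed transcription", {
  # keyed per equation as printed, independently of the registry layout
  published <- list(
    new_na_male = c(age = -0.191, bmi = 4.349, na = 0.229, ratio = 1.744,
                    const = 41.492),
    new_na_female = c(age = -1.030, bmi = 2.011, na = 0.143, ratio = 1.035,
                      const = 147.159),
    new_k_male = c(age = -0.052, bmi = 0.410, k = 0.031, lnkcr = 33.280,
                   lnnacr = -5.789, const = -1.035),
    new_k_female = c(age = -0.235, bmi = 0.530, k = 0.040, lnkcr = 30.990,
                     lnnacr = -7.837, const = 4.318),
    kawasaki_cr_male = c(w = 15.12, h = 7.39, a = -12.63, const = -79.90),
    kawasaki_cr_female = c(w = 8.58, h = 5.09, a = -4.72, const = -74.50),
    kawasaki_mult = c(na = 16.30, k = 7.20),
    tanaka_cr = c(w = 14.89, h = 16.14, a = -2.04, const = -2244.45),
    tanaka_mult = c(na = 21.98, k = 7.59),
    tanaka_exp = c(na = 0.392, k = 0.431),
    intersalt_male = c(const = 25.46, na = 0.46, cr = -2.75, k = -0.13,
                       bmi = 4.10, age = 0.26, age2 = 0),
    intersalt_female = c(const = 5.07, na = 0.34, cr = -2.16, k = -0.09,
                         bmi = 2.39, age = 2.35, age2 = -0.03))
  reg <- equation_registry()
  g <- function(m, a, s, t) reg$beta[reg$method == m & reg$analyte == a &
                                       reg$sex == s & reg$term == t]
  for (s in c("male", "female")) {
    p <- published[[paste0("new_na_", s)]]
    expect_equal(g("new", "na", s, "age"), unname(p["age"]))
    expect_equal(g("new", "na", s, "bmi"), unname(p["bmi"]))
    expect_equal(g("new", "na", s, "spot_na"), unname(p["na"]))
    expect_equal(g("new", "na", s, "na_cr_ratio"), unname(p["ratio"]))
    expect_equal(g("new", "na", s, "intercept"), unname(p["const"]))
    p <- published[[paste0("new_k_", s)]]
    expect_equal(g("new", "k", s, "age"), unname(p["age"]))
    expect_equal(g("new", "k", s, "bmi"), unname(p["bmi"]))
    expect_equal(g("new", "k", s, "spot_k"), unname(p["k"]))
    expect_equal(g("new", "k", s, "ln_k_cr"), unname(p["lnkcr"]))
    expect_equal(g("new", "k", s, "ln_na_cr"), unname(p["lnnacr"]))
    expect_equal(g("new", "k", s, "intercept"), unname(p["const"]))
    p <- published[[paste0("kawasaki_cr_", s)]]
    expect_equal(g("kawasaki", "prucr", s, "weight"), unname(p["w"]))
    expect_equal(g("kawasaki", "prucr", s, "height"), unname(p["h"]))
    expect_equal(g("kawasaki", "prucr", s, "age"), unname(p["a"]))
    expect_equal(g("kawasaki", "prucr", s, "intercept"), unname(p["const"]))
    p <- published[[paste0("intersalt_", s)]]
    for (nm in c("spot_na", "spot_cr", "spot_k", "bmi", "age", "age2",
                 "intercept")) {
      key <- c(spot_na = "na", spot_cr = "cr", spot_k = "k", bmi = "bmi",
               age = "age", age2 = "age2", intercept = "const")[[nm]]
      expect_equal(g("intersalt", "na", s, nm), unname(p[key]))
    }
  }
  for (an in c("na", "k")) {
    expect_equal(g("kawasaki", an, "both", "multiplier"),
                 unname(published$kawasaki_mult[an]))
    expect_equal(g("kawasaki", an, "both", "exponent"), 0.5)
    expect_equal(g("tanaka", an, "both", "multiplier"),
                 unname(published$tanaka_mult[an]))
    expect_equal(g("tanaka", an, "both", "exponent"),
                 unname(published$tanaka_exp[an]))
  }
  expect_equal(g("tanaka", "prucr", "both", "weight"), 14.89)
  expect_equal(g("tanaka", "prucr", "both", "height"), 16.14)
  expect_equal(g("tanaka", "prucr", "both", "age"), -2.04)
  expect_equal(g("tanaka", "prucr", "both", "intercept"), -2244.45)
})

test_that("batch evaluation reports inapplicable methods with reasons", {
  rec <- full_record()
  out <- estimate_all(rec)
  expect_true(all(c("est_na_new", "est_k_new", "est_na_kawasaki",
                    "est_k_kawasaki", "est_na_intersalt", "est_na_tanaka",
                    "est_k_tanaka", "prucr24h_kawasaki",
                    "prucr24h_tanaka") %in% names(out)))
  expect_false("est_k_intersalt" %in% names(out))
  expect_equal(nrow(attr(out, "missing")), 0)
  expect_equal(out$est_na_new, estimate_na_new("male", 65, rec$bmi, 130, 8.9))
  expect_equal(out$est_na_kawasaki,
               estimate_kawasaki("male", 70, 165, 65, 130, 8.9, "na"))

  # no anthropometry: Kawasaki and Tanaka flagged missing, others present
  rec2 <- full_record()
  rec2$height_cm <- NA; rec2$weight_kg <- NA
  out2 <- estimate_all(rec2)
  expect_true(is.na(out2$est_na_kawasaki))
  expect_false(is.na(out2$est_na_new))
  expect_false(is.na(out2$est_na_intersalt))
  miss <- attr(out2, "missing")
  expect_setequal(miss$method, c("kawasaki", "tanaka"))
  expect_true(all(nchar(miss$reason) > 0))

  # empty batch
  out0 <- estimate_all(full_record()[0, ])
  expect_equal(nrow(out0), 0)
})

test_that("BMI is reconciled with height and weight", {
  rec <- full_record()
  rec$bmi <- NA  # derived from height/weight
  out <- estimate_all(rec)
  expect_equal(out$est_na_new,
               estimate_na_new("male", 65, 70 / 1.65^2, 130, 8.9))
  rec$bmi <- 70 / 1.65^2 + 1  # disagrees by > 0.5
  expect_error(estimate_all(rec), "BMI")
})

test_that("negative estimates are flagged, not clipped", {
  rec <- full_record()
  rec$sex <- "F"; rec$age_y <- 89; rec$bmi <- 16; rec$height_cm <- 150
  rec$weight_kg <- 16 * 1.5^2
  rec$spot_na_mmol_l <- 6; rec$spot_k_mmol_l <- 3; rec$spot_cr_mmol_l <- 30
  out <- estimate_all(rec)
  expect_true(out$est_na_intersalt < 0)  # female -0.03*age^2 dominates
  expect_true(out$flag_negative)
})

test_that("cohort files round-trip through the canonical schema", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  co <- make_fixture("tiny")
  write_cohort(co, tmp)
  back <- read_cohort(tmp, require_24h = TRUE)
  expect_equal(back, co, tolerance = 1e-12)
  # missing-column diagnostic names the columns
  bad <- co[, setdiff(names(co), "spot_na_mmol_l")]
  write_cohort(bad, tmp)
  expect_error(read_cohort(tmp), "spot_na_mmol_l")
})
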