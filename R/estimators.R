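#' Estimate 24 h urinary sodium excretion with the new sex-specific formula
#'
#' Linear estimating equation developed in stroke patients:
#' age, BMI, spot sodium concentration, and the spot sodium-to-creatinine
#' ratio (both concentrations in mmol/L, so the ratio is dimensionless).
#' All arguments are vectorized and recycled to a common length.
#'
#' @param sex "male"/"female" (or "M"/"F").
#' @param age Age in years (> 0).
#' @param bmi Body-mass index, kg/m^2 (> 0).
#' @param spot_na Spot urinary sodium, mmol/L (>= 0).
#' @param spot_cr Spot urinary creatinine, mmol/L (> 0; divisor in the ratio).
#' @return Estimated 24 h sodium excretion, mmol/day. Negative values are
#'   possible for extreme covariates and are returned as-is with a warning.
#' @examples
#' estimate_na_new("male", age = 65, bmi = 25, spot_na = 130, spot_cr = 8.9)
#' @export
estimate_na_new <- function(sex, age, bmi, spot_na, spot_cr) {
  sex <- check_sex(sex)
  check_num(age, "age", 0, strict = TRUE)
  check_num(bmi, "bmi", 0, strict = TRUE)
  check_num(spot_na, "spot_na", 0)
  check_num(spot_cr, "spot_cr", 0, strict = TRUE)
  n <- max(length(sex), length(age), length(bmi), length(spot_na), length(spot_cr))
  sex <- rep_len(sex, n); age <- rep_len(age, n); bmi <- rep_len(bmi, n)
  spot_na <- rep_len(spot_na, n); spot_cr <- rep_len(spot_cr, n)
  out <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    b <- reg_coefs("new", "na", s)
    out[i] <- b["intercept"] + b["age"] * age[i] + b["bmi"] * bmi[i] +
      b["spot_na"] * spot_na[i] + b["na_cr_ratio"] * spot_na[i] / spot_cr[i]
  }
  warn_negative(out, "sodium")
}

#' Estimate 24 h urinary potassium excretion with the new sex-specific formula
#'
#' Uses age, BMI, spot potassium, and the natural logs of the potassium- and
#' sodium-to-creatinine ratios (all concentrations mmol/L). Positive spot
#' sodium, potassium and creatinine are required because both log ratios
#' enter the equation.
#'
#' @inheritParams estimate_na_new
#' @param spot_k Spot urinary potassium, mmol/L (> 0).
#' @return Estimated 24 h potassium excretion, mmol/day.
#' @examples
#' estimate_k_new("female", age = 65, bmi = 25, spot_k = 55,
#'                spot_na = 130, spot_cr = 8.9)
#' @export
estimate_k_new <- function(sex, age, bmi, spot_k, spot_na, spot_cr) {
  sex <- check_sex(sex)
  check_num(age, "age", 0, strict = TRUE)
  check_num(bmi, "bmi", 0, strict = TRUE)
  check_num(spot_k, "spot_k", 0, strict = TRUE)
  check_num(spot_na, "spot_na", 0, strict = TRUE)
  check_num(spot_cr, "spot_cr", 0, strict = TRUE)
  n <- max(length(sex), length(age), length(bmi), length(spot_k),
           length(spot_na), length(spot_cr))
  sex <- rep_len(sex, n); age <- rep_len(age, n); bmi <- rep_len(bmi, n)
  spot_k <- rep_len(spot_k, n); spot_na <- rep_len(spot_na, n)
  spot_cr <- rep_len(spot_cr, n)
  out <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    b <- reg_coefs("new", "k", s)
    out[i] <- b["intercept"] + b["age"] * age[i] + b["bmi"] * bmi[i] +
      b["spot_k"] * spot_k[i] +
      b["ln_k_cr"] * log(spot_k[i] / spot_cr[i]) +
      b["ln_na_cr"] * log(spot_na[i] / spot_cr[i])
  }
  warn_negative(out, "potassium")
}

warn_negative <- function(x, what) {
  if (any(x < 0, na.rm = TRUE))
    warning(sprintf("%d negative %s estimate(s) returned unclipped",
                    sum(x < 0, na.rm = TRUE), what), call. = FALSE)
  x
}

#' Predicted 24 h urinary creatinine excretion (Kawasaki sub-model)
#'
#' Sex-specific anthropometric prediction in mg/day from weight, height and
#' age. A non-positive prediction means the anthropometry is outside the
#' formula's domain and is an error.
#'
#' @param sex "male"/"female".
#' @param weight Body weight, kg (> 0).
#' @param height Height, cm (> 0).
#' @param age Age, years (> 0).
#' @return Predicted creatinine excretion, mg/day (strictly positive).
#' @export
predict_creatinine_kawasaki <- function(sex, weight, height, age) {
  sex <- check_sex(sex)
  check_num(weight, "weight", 0, strict = TRUE)
  check_num(height, "height", 0, strict = TRUE)
  check_num(age, "age", 0, strict = TRUE)
  n <- max(length(sex), length(weight), length(height), length(age))
  sex <- rep_len(sex, n); weight <- rep_len(weight, n)
  height <- rep_len(height, n); age <- rep_len(age, n)
  out <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    b <- reg_coefs("kawasaki", "prucr", s)
    out[i] <- b["weight"] * weight[i] + b["height"] * height[i] +
      b["age"] * age[i] + b["intercept"]
  }
  if (any(out <= 0))
    stop("predicted 24 h creatinine <= 0: anthropometry outside formula domain",
         call. = FALSE)
  out
}

#' Predicted 24 h urinary creatinine excretion (Tanaka sub-model)
#'
#' Sex-free anthropometric prediction in mg/day.
#'
#' @inheritParams predict_creatinine_kawasaki
#' @return Predicted creatinine excretion, mg/day (strictly positive).
#' @export
predict_creatinine_tanaka <- function(weight, height, age) {
  check_num(weight, "weight", 0, strict = TRUE)
  check_num(height, "height", 0, strict = TRUE)
  check_num(age, "age", 0, strict = TRUE)
  b <- reg_coefs("tanaka", "prucr")
  out <- b["weight"] * weight + b["height"] * height + b["age"] * age +
    b["intercept"]
  out <- unname(out)
  if (any(out <= 0))
    stop("predicted 24 h creatinine <= 0: anthropometry outside formula domain",
         call. = FALSE)
  out
}

# shared power-law core of Kawasaki/Tanaka: mult * (conc / cr_mg_l * prucr)^exp
power_law_estimate <- function(method, analyte, conc, spot_cr, prucr) {
  b <- reg_coefs(method, analyte)
  x <- conc / cr_mmol_to_mg(spot_cr) * prucr
  unname(b["multiplier"] * x ^ b["exponent"])
}

#' Kawasaki estimate of 24 h sodium or potassium excretion
#'
#' Power-law formula: multiplier times the square root of the spot
#' concentration-to-creatinine ratio (creatinine in mg/L) scaled by the
#' sex-specific predicted 24 h creatinine excretion.
#'
#' @inheritParams predict_creatinine_kawasaki
#' @param spot_conc Spot concentration of the analyte, mmol/L (>= 0).
#' @param spot_cr Spot creatinine, mmol/L (> 0); converted internally to mg/L.
#' @param analyte "na" or "k".
#' @return Estimated 24 h excretion, mmol/day.
#' @export
estimate_kawasaki <- function(sex, weight, height, age, spot_conc, spot_cr,
                              analyte = c("na", "k")) {
  analyte <- match.arg(analyte)
  check_num(spot_conc, "spot_conc", 0)
  check_num(spot_cr, "spot_cr", 0, strict = TRUE)
  prucr <- predict_creatinine_kawasaki(sex, weight, height, age)
  power_law_estimate("kawasaki", analyte, spot_conc, spot_cr, prucr)
}

#' Tanaka estimate of 24 h sodium or potassium excretion
#'
#' @inheritParams estimate_kawasaki
#' @return Estimated 24 h excretion, mmol/day.
#' @export
estimate_tanaka <- function(weight, height, age, spot_conc, spot_cr,
                            analyte = c("na", "k")) {
  analyte <- match.arg(analyte)
  check_num(spot_conc, "spot_conc", 0)
  check_num(spot_cr, "spot_cr", 0, strict = TRUE)
  prucr <- predict_creatinine_tanaka(weight, height, age)
  power_law_estimate("tanaka", analyte, spot_conc, spot_cr, prucr)
}

#' INTERSALT estimate of 24 h sodium excretion
#'
#' Sex-specific linear equation in spot sodium, creatinine (kept in mmol/L —
#' no unit conversion here), potassium, BMI and age; the female equation
#' carries an additional quadratic age term. No potassium counterpart is
#' published for this family.
#'
#' @inheritParams estimate_na_new
#' @param spot_k Spot urinary potassium, mmol/L (>= 0).
#' @return Estimated 24 h sodium excretion, mmol/day.
#' @export
estimate_na_intersalt <- function(sex, age, bmi, spot_na, spot_k, spot_cr) {
  sex <- check_sex(sex)
  check_num(age, "age", 0, strict = TRUE)
  check_num(bmi, "bmi", 0, strict = TRUE)
  check_num(spot_na, "spot_na", 0)
  check_num(spot_k, "spot_k", 0)
  check_num(spot_cr, "spot_cr", 0)
  n <- max(length(sex), length(age), length(bmi), length(spot_na),
           length(spot_k), length(spot_cr))
  sex <- rep_len(sex, n); age <- rep_len(age, n); bmi <- rep_len(bmi, n)
  spot_na <- rep_len(spot_na, n); spot_k <- rep_len(spot_k, n)
  spot_cr <- rep_len(spot_cr, n)
  out <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    b <- reg_coefs("intersalt", "na", s)
    out[i] <- b["intercept"] + b["spot_na"] * spot_na[i] +
      b["spot_cr"] * spot_cr[i] + b["spot_k"] * spot_k[i] +
      b["bmi"] * bmi[i] + b["age"] * age[i] + b["age2"] * age[i]^2
  }
  warn_negative(out, "sodium")
}

# resolve BMI from the record: prefer the reported value, fall back to
# height/weight; reported-vs-derived mismatch beyond 0.5 kg/m^2 is an error
resolve_bmi <- function(bmi, height_cm, weight_kg) {
  derived <- weight_kg / (height_cm / 100)^2
  out <- ifelse(is.na(bmi), derived, bmi)
  both <- !is.na(bmi) & !is.na(derived)
  if (any(both & abs(bmi - derived) > 0.5))
    stop("reported BMI disagrees with height/weight by more than 0.5 kg/m^2",
         call. = FALSE)
  out
}

#' Evaluate all estimating equations over a batch of records
#'
#' Takes a cohort data frame in the canonical column schema (see
#' [read_cohort()]) and appends, for each applicable method, estimated 24 h
#' sodium and potassium columns (`est_na_<method>`, `est_k_<method>`) and the
#' Kawasaki/Tanaka predicted-creatinine intermediates (`prucr24h_<method>`,
#' mg/day). Records lacking the inputs a method needs (e.g. height/weight for
#' the anthropometric formulas) get `NA` there and are listed, with a reason,
#' in the `"missing"` attribute rather than silently dropped.
#'
#' @param records Data frame with columns `id`, `sex`, `age_y`, `bmi` (or
#'   `height_cm` + `weight_kg`), `spot_na_mmol_l`, `spot_k_mmol_l`,
#'   `spot_cr_mmol_l`.
#' @param methods Character subset of `c("new","kawasaki","intersalt","tanaka")`.
#' @return `records` with estimate columns appended; attribute `"missing"` is
#'   a data.frame of (id, method, reason).
#' @export
estimate_all <- function(records,
                         methods = c("new", "kawasaki", "intersalt", "tanaka")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (nrow(records) == 0L) {
    attr(records, "missing") <- data.frame(id = character(), method = character(),
                                           reason = character())
    return(records)
  }
  need <- c("id", "sex", "age_y", "spot_na_mmol_l", "spot_k_mmol_l",
            "spot_cr_mmol_l")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sex <- check_sex(records$sex)
  h <- if ("height_cm" %in% names(records)) records$height_cm else NA_real_
  w <- if ("weight_kg" %in% names(records)) records$weight_kg else NA_real_
  bmi0 <- if ("bmi" %in% names(records)) records$bmi else NA_real_
  bmi <- resolve_bmi(bmi0, h, w)
  age <- records$age_y
  na <- records$spot_na_mmol_l; k <- records$spot_k_mmol_l
  cr <- records$spot_cr_mmol_l
  h <- rep_len(h, nrow(records)); w <- rep_len(w, nrow(records))
  missing_log <- list()
  note <- function(ids, method, reason) {
    if (length(ids))
      missing_log[[length(missing_log) + 1L]] <<-
        data.frame(id = as.character(ids), method = method, reason = reason)
  }
  base_ok <- !is.na(age) & !is.na(bmi) & !is.na(na) & !is.na(k) &
    !is.na(cr) & cr > 0
  anthro_ok <- base_ok & !is.na(h) & !is.na(w) & h > 0 & w > 0

  if ("new" %in% methods) {
    ok <- base_ok & na > 0 & k > 0
    records$est_na_new <- records$est_k_new <- NA_real_
    okna <- base_ok
    records$est_na_new[okna] <- suppressWarnings(
      estimate_na_new(sex[okna], age[okna], bmi[okna], na[okna], cr[okna]))
    records$est_k_new[ok] <- suppressWarnings(
      estimate_k_new(sex[ok], age[ok], bmi[ok], k[ok], na[ok], cr[ok]))
    note(records$id[!okna], "new", "covariates or spot measurements missing")
    note(records$id[okna & !ok], "new",
         "non-positive spot Na or K (log ratio undefined)")
  }
  if ("kawasaki" %in% methods) {
    records$est_na_kawasaki <- records$est_k_kawasaki <-
      records$prucr24h_kawasaki <- NA_real_
    if (any(anthro_ok)) {
      i <- anthro_ok
      records$prucr24h_kawasaki[i] <-
        predict_creatinine_kawasaki(sex[i], w[i], h[i], age[i])
      records$est_na_kawasaki[i] <-
        estimate_kawasaki(sex[i], w[i], h[i], age[i], na[i], cr[i], "na")
      records$est_k_kawasaki[i] <-
        estimate_kawasaki(sex[i], w[i], h[i], age[i], k[i], cr[i], "k")
    }
    note(records$id[!anthro_ok], "kawasaki",
         "height/weight (or spot measurements) missing")
  }
  if ("intersalt" %in% methods) {
    records$est_na_intersalt <- NA_real_
    records$est_na_intersalt[base_ok] <- suppressWarnings(
      estimate_na_intersalt(sex[base_ok], age[base_ok], bmi[base_ok],
                            na[base_ok], k[base_ok], cr[base_ok]))
    note(records$id[!base_ok], "intersalt",
         "covariates or spot measurements missing")
  }
  if ("tanaka" %in% methods) {
    records$est_na_tanaka <- records$est_k_tanaka <-
      records$prucr24h_tanaka <- NA_real_
    if (any(anthro_ok)) {
      i <- anthro_ok
      records$prucr24h_tanaka[i] <- predict_creatinine_tanaka(w[i], h[i], age[i])
      records$est_na_tanaka[i] <-
        estimate_tanaka(w[i], h[i], age[i], na[i], cr[i], "na")
      records$est_k_tanaka[i] <-
        estimate_tanaka(w[i], h[i], age[i], k[i], cr[i], "k")
    }
    note(records$id[!anthro_ok], "tanaka",
         "height/weight (or spot measurements) missing")
  }
  est_cols <- grep("^est_", names(records), value = TRUE)
  records$flag_negative <-
    rowSums(as.matrix(records[est_cols]) < 0, na.rm = TRUE) > 0
  attr(records, "missing") <-
    if (length(missing_log)) do.call(rbind, missing_log)
    else data.frame(id = character(), method = character(), reason = character())
  records
}
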