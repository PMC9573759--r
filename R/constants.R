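#' Unit-conversion constants
#'
#' Creatinine molar mass 113.12 g/mol converts mmol/L to mg/L (the
#' anthropometric formulas take spot creatinine in mg/L while the assay
#' reports mmol/L); 58.44 g/mol NaCl converts mmol sodium to grams of salt.
#' @name units
NULL

CREATININE_MG_PER_MMOL <- 113.12
NACL_G_PER_MMOL_NA <- 0.05844

#' Convert urinary creatinine from mmol/L to mg/L
#'
#' @param cr Creatinine concentration, mmol/L (non-negative).
#' @return Concentration in mg/L.
#' @examples
#' cr_mmol_to_mg(8.93)
#' @export
cr_mmol_to_mg <- function(cr) {
  check_num(cr, "cr", lower = 0)
  cr * CREATININE_MG_PER_MMOL
}

#' Convert millimoles of sodium to grams of salt (NaCl)
#'
#' Uses the conventional 58.44 g/mol molar mass of NaCl, so 17.1 mmol of
#' sodium is about 1 g of salt. Rounding is left to the caller.
#'
#' @param na Sodium amount, mmol (non-negative).
#' @return Grams of NaCl.
#' @examples
#' na_mmol_to_g_salt(12.30) # ~0.72 g
#' @export
na_mmol_to_g_salt <- function(na) {
  check_num(na, "na", lower = 0)
  na * NACL_G_PER_MMOL_NA
}

# ---------------------------------------------------------------------------
# Coefficient registry: every printed coefficient of the new sex-specific
# equations and the three published comparator formulas lives in this one
# table, keyed by (method, analyte, sex, term). Estimator code reads from
# here only; a transcription-guard test compares it against an independently
# keyed copy.
# ---------------------------------------------------------------------------

.registry <- local({
  row <- function(method, analyte, sex, term, beta)
    data.frame(method = method, analyte = analyte, sex = sex,
               term = term, beta = beta, stringsAsFactors = FALSE)
  rbind(
    # new formula, sodium (mmol/day)
    row("new", "na", "male",   c("intercept", "age", "bmi", "spot_na", "na_cr_ratio"),
        c(41.492, -0.191, 4.349, 0.229, 1.744)),
    row("new", "na", "female", c("intercept", "age", "bmi", "spot_na", "na_cr_ratio"),
        c(147.159, -1.030, 2.011, 0.143, 1.035)),
    # new formula, potassium (mmol/day)
    row("new", "k", "male",   c("intercept", "age", "bmi", "spot_k", "ln_k_cr", "ln_na_cr"),
        c(-1.035, -0.052, 0.410, 0.031, 33.280, -5.789)),
    row("new", "k", "female", c("intercept", "age", "bmi", "spot_k", "ln_k_cr", "ln_na_cr"),
        c(4.318, -0.235, 0.530, 0.040, 30.990, -7.837)),
    # Kawasaki predicted 24 h creatinine (mg/day), sex-specific
    row("kawasaki", "prucr", "male",   c("weight", "height", "age", "intercept"),
        c(15.12, 7.39, -12.63, -79.90)),
    row("kawasaki", "prucr", "female", c("weight", "height", "age", "intercept"),
        c(8.58, 5.09, -4.72, -74.50)),
    # Kawasaki power-law multipliers, exponent 0.5
    row("kawasaki", "na", "both", c("multiplier", "exponent"), c(16.30, 0.5)),
    row("kawasaki", "k",  "both", c("multiplier", "exponent"), c(7.20, 0.5)),
    # Tanaka predicted 24 h creatinine (mg/day), sex-free
    row("tanaka", "prucr", "both", c("weight", "height", "age", "intercept"),
        c(14.89, 16.14, -2.04, -2244.45)),
    row("tanaka", "na", "both", c("multiplier", "exponent"), c(21.98, 0.392)),
    row("tanaka", "k",  "both", c("multiplier", "exponent"), c(7.59, 0.431)),
    # INTERSALT sodium (no potassium equation is published in this family);
    # spot creatinine stays in mmol/L here
    row("intersalt", "na", "male",
        c("intercept", "spot_na", "spot_cr", "spot_k", "bmi", "age", "age2"),
        c(25.46, 0.46, -2.75, -0.13, 4.10, 0.26, 0)),
    row("intersalt", "na", "female",
        c("intercept", "spot_na", "spot_cr", "spot_k", "bmi", "age", "age2"),
        c(5.07, 0.34, -2.16, -0.09, 2.39, 2.35, -0.03))
  )
})

#' Coefficient registry of all estimating equations
#'
#' Returns the single table all estimator functions read their printed
#' coefficients from: the new sex-specific sodium/potassium equations, the
#' Kawasaki and Tanaka power-law formulas with their predicted-creatinine
#' sub-models, and the INTERSALT sodium equations.
#'
#' @return A data.frame with columns `method`, `analyte`, `sex`, `term`, `beta`.
#' @export
equation_registry <- function() .registry

# named coefficient vector for one equation
reg_coefs <- function(method, analyte, sex = "both") {
  r <- .registry[.registry$method == method & .registry$analyte == analyte &
                 .registry$sex == sex, ]
  if (nrow(r) == 0L)
    stop(sprintf("no registry entry for %s/%s/%s", method, analyte, sex),
         call. = FALSE)
  stats::setNames(r$beta, r$term)
}
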