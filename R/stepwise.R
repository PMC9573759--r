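#' Random train/test split of a cohort
#'
#' Uniform random partition without replacement; the training size is
#' `round(n * train_fraction)` (round-half-even). Reproducible for a fixed
#' seed and independent of the caller's RNG state.
#'
#' @param records Data frame (one row per participant).
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_train_test <- function(records, train_fraction = 0.7, seed = 1L) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

# partial-F stepwise loop on an lm scope; returns final lm
run_stepwise <- function(response, terms, data, entry_p, stay_p,
                         max_steps = 100L) {
  current <- character()
  f0 <- stats::as.formula(paste(response, "~ 1"))
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    fit <- fit_ols(response, current, data)
    # forward: best candidate by partial-F p value
    pool <- setdiff(terms, current)
    if (length(pool)) {
      a1 <- stats::add1(fit, scope = make_formula(response, union(current, pool),
                                                  rhs_only = TRUE),
                        test = "F")
      p <- a1[["Pr(>F)"]][-1L]
      names(p) <- gsub("`", "", rownames(a1)[-1L])
      p <- p[!is.na(p)]
      if (length(p) && min(p) < entry_p) {
        current <- c(current, names(p)[which.min(p)])
        fit <- fit_ols(response, current, data)
        changed <- TRUE
      }
    }
    # backward: worst retained term by partial-F p value
    if (length(current)) {
      d1 <- stats::drop1(fit, test = "F")
      p <- d1[["Pr(>F)"]][-1L]
      names(p) <- gsub("`", "", rownames(d1)[-1L])
      p <- p[!is.na(p)]
      if (length(p) && max(p) > stay_p) {
        current <- setdiff(current, names(p)[which.max(p)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current
}

make_formula <- function(response, terms, rhs_only = FALSE) {
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ")
         else "1"
  stats::as.formula(paste(if (rhs_only) "~" else paste(response, "~"), rhs))
}

# lm wrapper whose formula environment carries the data, so add1/drop1 can
# re-evaluate the fit
fit_ols <- function(response, terms, data) {
  f <- make_formula(response, terms)
  environment(f) <- environment()
  stats::lm(f, data = data)
}

#' Stepwise multiple linear regression with an OLS refit
#'
#' Forward-selection / backward-elimination driven by the partial-F p value
#' of each single term (enter while the best candidate has p < `entry_p`,
#' remove while the worst retained term has p > `stay_p`), followed by an
#' ordinary-least-squares fit on the retained terms. With
#' `entry_p = stay_p = 1` selection is disabled and the result is plain OLS
#' on the full candidate set. Aliased (perfectly collinear) terms are dropped
#' with a warning before selection.
#'
#' @param formula Model formula giving the outcome and the full candidate
#'   term set, e.g. `y ~ age + bmi + spot_na + na_cr_ratio`.
#' @param data Data frame with the variables of `formula`.
#' @param entry_p Partial-F p value below which a candidate enters (0.05).
#' @param stay_p Partial-F p value above which a retained term leaves (0.10).
#'   Must satisfy `entry_p <= stay_p`.
#' @param select Run selection? If `FALSE`, all candidates are kept.
#' @return Object of class `stepwise_lm`: the final [stats::lm] fit plus a
#'   coefficient table (`term`, `beta`, `se`, `t`, `p`), the multiple
#'   correlation `R`, `n`, and the retained/removed term sets. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `fitted`.
#' @examples
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
#' d$y <- 2 * d$x1 + rnorm(100)
#' stepwise_lm(y ~ x1 + x2, d)
#' @export
stepwise_lm <- function(formula, data, entry_p = 0.05, stay_p = 0.10,
                        select = TRUE) {
  if (entry_p > stay_p)
    stop("entry_p must not exceed stay_p (prevents cycling)", call. = FALSE)
  response <- all.vars(formula)[1L]
  terms <- labels(stats::terms(formula, data = data))
  if (nrow(data) < length(terms) + 2L)
    stop("too few rows for the candidate set", call. = FALSE)

  # drop aliased candidates up front (rank-deficient full design)
  full <- fit_ols(response, terms, data)
  aliased <- names(which(is.na(stats::coef(full))))
  aliased <- gsub("`", "", aliased)
  if (length(aliased)) {
    warning("dropping collinear term(s): ", paste(aliased, collapse = ", "),
            call. = FALSE)
    terms <- setdiff(terms, aliased)
  }

  retained <- if (select) {
    run_stepwise(response, terms, data, entry_p, stay_p)
  } else terms
  if (select && length(retained) == 0L)
    warning("no candidate met the entry criterion; intercept-only model",
            call. = FALSE)
  fit <- fit_ols(response, retained, data)
  sm <- summary(fit)
  ct <- stats::coef(sm)
  tab <- data.frame(term = gsub("`", "", rownames(ct)),
                    beta = ct[, 1], se = ct[, 2], t = ct[, 3], p = ct[, 4],
                    row.names = NULL)
  tab$term[tab$term == "(Intercept)"] <- "intercept"
  structure(list(fit = fit, table = tab,
                 R = sqrt(max(0, sm$r.squared)),
                 n = stats::nobs(fit),
                 retained = retained,
                 removed = setdiff(terms, retained),
                 aliased = aliased,
                 entry_p = entry_p, stay_p = stay_p, select = select,
                 response = response, candidates = terms,
                 call = match.call()),
            class = "stepwise_lm")
}

#' @export
print.stepwise_lm <- function(x, digits = 4, ...) {
  cat(sprintf("Stepwise linear model: %s ~ %s\n", x$response,
              if (length(x$retained)) paste(x$retained, collapse = " + ")
              else "1"))
  cat(sprintf("  n = %d, multiple correlation R = %.3f\n", x$n, x$R))
  tab <- x$table
  tab$beta <- signif(tab$beta, digits); tab$se <- signif(tab$se, digits)
  tab$t <- signif(tab$t, digits)
  tab$p <- format.pval(tab$p, digits = 3, eps = 1e-3)
  print(tab, row.names = FALSE)
  if (length(x$removed))
    cat("  removed by selection:", paste(x$removed, collapse = ", "), "\n")
  if (length(x$aliased))
    cat("  dropped as collinear:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.stepwise_lm <- function(object, ...) {
  out <- object$table
  attr(out, "R") <- object$R
  attr(out, "n") <- object$n
  out
}

#' @export
coef.stepwise_lm <- function(object, ...) {
  stats::setNames(object$table$beta, object$table$term)
}

#' @export
predict.stepwise_lm <- function(object, newdata = NULL, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.stepwise_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.stepwise_lm <- function(object, ...) stats::fitted(object$fit)

# derived regression terms of the estimating equations
add_model_terms <- function(df) {
  df$na_cr_ratio <- df$spot_na_mmol_l / df$spot_cr_mmol_l
  df$ln_k_cr <- log(df$spot_k_mmol_l / df$spot_cr_mmol_l)
  df$ln_na_cr <- log(df$spot_na_mmol_l / df$spot_cr_mmol_l)
  df
}

paper_term_sets <- list(
  na = c("age_y", "bmi", "spot_na_mmol_l", "na_cr_ratio"),
  k  = c("age_y", "bmi", "spot_k_mmol_l", "ln_k_cr", "ln_na_cr")
)

#' Fit the four sex-specific estimating equations on training data
#'
#' Reproduces the development step: per sex and per outcome (24 h sodium,
#' 24 h potassium), fit the published candidate term sets — sodium: age, BMI,
#' spot sodium, sodium/creatinine ratio; potassium: age, BMI, spot potassium,
#' ln(K/Cr), ln(Na/Cr) — by [stepwise_lm()]. By default selection is enabled;
#' if selection removes a published term this is reported, not an error.
#'
#' @param train Training data frame in the canonical schema with measured
#'   `u24_na_mmol` and `u24_k_mmol`.
#' @param select Run stepwise selection (default) or plain OLS on the full
#'   term sets.
#' @param entry_p,stay_p Selection thresholds, see [stepwise_lm()].
#' @return Object of class `excretion_models`: named list of up to four
#'   `stepwise_lm` fits (`na_male`, `na_female`, `k_male`, `k_female`).
#'   Sexes absent from `train` yield a warning and a partial result.
#' @export
fit_excretion_models <- function(train, select = TRUE, entry_p = 0.05,
                                 stay_p = 0.10) {
  train <- add_model_terms(train)
  out <- list()
  for (s in c("male", "female")) {
    sub <- train[check_sex(train$sex) == s, , drop = FALSE]
    for (oc in c("na", "k")) {
      key <- paste(oc, s, sep = "_")
      terms <- paper_term_sets[[oc]]
      response <- if (oc == "na") "u24_na_mmol" else "u24_k_mmol"
      if (nrow(sub) < length(terms) + 2L) {
        warning(sprintf("too few %s records; model %s skipped", s, key),
                call. = FALSE)
        next
      }
      m <- stepwise_lm(make_formula(response, terms), sub,
                       entry_p = entry_p, stay_p = stay_p, select = select)
      if (length(m$removed))
        message(sprintf("model %s: selection removed %s", key,
                        paste(m$removed, collapse = ", ")))
      out[[key]] <- m
    }
  }
  if (length(out) < 4L)
    warning("partial output: not all sex/outcome models could be fitted",
            call. = FALSE)
  structure(out, class = "excretion_models")
}

#' @export
print.excretion_models <- function(x, ...) {
  cat("Sex-specific 24 h excretion estimating equations\n\n")
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]], ...)
    cat("\n")
  }
  invisible(x)
}

#' Coefficient tables of fitted estimating equations
#'
#' Binds the per-model coefficient tables (term, beta, SE, t, p plus R and n)
#' into one long data frame, mirroring the published presentation of the
#' development step.
#'
#' @param x An `excretion_models` object.
#' @param ... Unused.
#' @return A data.frame with columns `model`, `term`, `beta`, `se`, `t`,
#'   `p`, `R`, `n`.
#' @export
as.data.frame.excretion_models <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    tab <- x[[nm]]$table
    cbind(model = nm, tab, R = x[[nm]]$R, n = x[[nm]]$n)
  }))
}

#' Predict 24 h excretion from fitted estimating equations
#'
#' @param object An `excretion_models` object.
#' @param newdata Data frame in the canonical schema.
#' @param ... Unused.
#' @return `newdata` with `est_na_fitted` / `est_k_fitted` columns appended.
#' @export
predict.excretion_models <- function(object, newdata, ...) {
  nd <- add_model_terms(newdata)
  sex <- check_sex(nd$sex)
  nd$est_na_fitted <- NA_real_
  nd$est_k_fitted <- NA_real_
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    kna <- paste0("na_", s); kk <- paste0("k_", s)
    if (!is.null(object[[kna]]))
      nd$est_na_fitted[i] <- predict(object[[kna]], nd[i, , drop = FALSE])
    if (!is.null(object[[kk]]))
      nd$est_k_fitted[i] <- predict(object[[kk]], nd[i, , drop = FALSE])
  }
  newdata$est_na_fitted <- nd$est_na_fitted
  newdata$est_k_fitted <- nd$est_k_fitted
  newdata
}
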