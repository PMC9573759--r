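#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the Mersenne-Twister stream seeded at `seed`, then
#' restores the caller's RNG state, so seeded package functions never
#' perturb the global random stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar-ish numeric argument check
check_num <- function(x, name, lower = -Inf, strict = FALSE, allow_na = FALSE) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  bad <- if (strict) x <= lower else x < lower
  bad <- bad & !is.na(x)
  if (any(bad)) {
    stop(sprintf("'%s' must be %s %s (got %s)", name,
                 if (strict) ">" else ">=", format(lower),
                 format(x[bad][1L])), call. = FALSE)
  }
  if (!allow_na && anyNA(x)) stop(sprintf("'%s' contains NA", name), call. = FALSE)
  invisible(x)
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  sex[sex %in% c("M", "m")] <- "male"
  sex[sex %in% c("F", "f")] <- "female"
  if (!all(sex %in% c("male", "female")))
    stop("'sex' must be one of 'male'/'female' (or 'M'/'F')", call. = FALSE)
  sex
}
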