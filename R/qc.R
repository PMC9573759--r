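#' Quality-control configuration for paired urine specimens
#'
#' Thresholds of the specimen-exclusion rules, in the order they are applied:
#' \enumerate{
#'   \item self-reported missed urine volume over 20\% of the total volume
#'     (total = collected + missed);
#'   \item total 24 h urine volume under 0.5 L;
#'   \item 24 h urinary creatinine excretion outside 4--25 mmol/day in women
#'     or 6--30 mmol/day in men (strict inequalities: boundary values kept);
#'   \item 24 h urine volume more than 3 SD from the population mean;
#'   \item spot creatinine concentration more than 3 SD from the population
#'     mean.
#' }
#' The 3-SD rules are two-sided and use the mean and SD computed once over
#' records surviving rules 1--3.
#'
#' @param missed_fraction_max Maximal missed/(collected+missed) fraction (0.20).
#' @param volume_min Minimal 24 h volume, L (0.5).
#' @param cr24_bounds_female,cr24_bounds_male Kept range of 24 h creatinine,
#'   mmol/day.
#' @param sd_multiplier SD multiplier of rules 4--5 (3).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(missed_fraction_max = 0.20, volume_min = 0.5,
                      cr24_bounds_female = c(4, 25),
                      cr24_bounds_male = c(6, 30),
                      sd_multiplier = 3) {
  check_num(missed_fraction_max, "missed_fraction_max", 0, strict = TRUE)
  check_num(volume_min, "volume_min", 0, strict = TRUE)
  check_num(sd_multiplier, "sd_multiplier", 0, strict = TRUE)
  for (b in list(cr24_bounds_female, cr24_bounds_male))
    if (length(b) != 2L || any(b <= 0) || b[1] >= b[2])
      stop("creatinine bounds must be a positive ordered pair", call. = FALSE)
  structure(list(missed_fraction_max = missed_fraction_max,
                 volume_min = volume_min,
                 cr24_bounds_female = cr24_bounds_female,
                 cr24_bounds_male = cr24_bounds_male,
                 sd_multiplier = sd_multiplier),
            class = "qc_config")
}

#' Apply the specimen-exclusion rules to paired spot/24 h records
#'
#' Evaluates all five rules of [qc_config()] on every record; a record may
#' accrue multiple reason codes. The reason codes are stable strings:
#' `missed_fraction`, `volume_low`, `cr24_out_of_range`, `volume_3sd`,
#' `spotcr_3sd`. The 3-SD rules are skipped (and flagged in the report) when
#' fewer than 3 records survive rules 1--3.
#'
#' @param records Data frame in the canonical schema with 24 h columns
#'   (`u24_vol_l`, `u24_cr_mmol`, `missed_l`, `spot_cr_mmol_l`, `sex`).
#' @param config A [qc_config()].
#' @return An object of class `qc_report`: list with `kept` (data frame),
#'   `excluded` (data frame of id + semicolon-joined reasons), `reasons`
#'   (long data frame id/reason), `counts` (per-rule exclusion counts),
#'   `stats` (means/SDs used by the SD rules), `sd_rules_applied`.
#' @export
apply_exclusions <- function(records, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  empty <- function() {
    structure(list(kept = records, excluded = data.frame(id = character(),
                                                         reasons = character()),
                   reasons = data.frame(id = character(), reason = character()),
                   counts = c(missed_fraction = 0L, volume_low = 0L,
                              cr24_out_of_range = 0L, volume_3sd = 0L,
                              spotcr_3sd = 0L),
                   stats = NULL, sd_rules_applied = FALSE,
                   n_input = nrow(records)),
              class = "qc_report")
  }
  if (nrow(records) == 0L) return(empty())
  need <- c("id", "sex", "u24_vol_l", "u24_cr_mmol", "missed_l",
            "spot_cr_mmol_l")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sex <- check_sex(records$sex)
  vol <- records$u24_vol_l
  missed <- ifelse(is.na(records$missed_l), 0, records$missed_l)
  cr24 <- records$u24_cr_mmol
  spotcr <- records$spot_cr_mmol_l

  # rules 1-3, printed order; strict inequalities throughout
  r1 <- missed / (vol + missed) > config$missed_fraction_max
  r2 <- vol < config$volume_min
  lo <- ifelse(sex == "female", config$cr24_bounds_female[1],
               config$cr24_bounds_male[1])
  hi <- ifelse(sex == "female", config$cr24_bounds_female[2],
               config$cr24_bounds_male[2])
  r3 <- cr24 < lo | cr24 > hi
  r1[is.na(r1)] <- FALSE; r2[is.na(r2)] <- FALSE; r3[is.na(r3)] <- FALSE

  surv13 <- !(r1 | r2 | r3)
  sd_ok <- sum(surv13) >= 3L
  stats <- NULL
  r4 <- r5 <- rep(FALSE, nrow(records))
  if (sd_ok) {
    stats <- list(vol_mean = mean(vol[surv13]), vol_sd = stats::sd(vol[surv13]),
                  spotcr_mean = mean(spotcr[surv13]),
                  spotcr_sd = stats::sd(spotcr[surv13]))
    m <- config$sd_multiplier
    # SD rules are evaluated on the survivors of rules 1-3 only: samples
    # already excluded are out of the population these rules screen
    r4 <- surv13 & abs(vol - stats$vol_mean) > m * stats$vol_sd
    r5 <- surv13 & abs(spotcr - stats$spotcr_mean) > m * stats$spotcr_sd
    r4[is.na(r4)] <- FALSE; r5[is.na(r5)] <- FALSE
  } else {
    warning("fewer than 3 records survive rules 1-3; 3-SD rules skipped",
            call. = FALSE)
  }

  flags <- cbind(missed_fraction = r1, volume_low = r2, cr24_out_of_range = r3,
                 volume_3sd = r4, spotcr_3sd = r5)
  drop <- rowSums(flags) > 0
  reasons_long <- do.call(rbind, lapply(which(drop), function(i) {
    data.frame(id = as.character(records$id[i]),
               reason = colnames(flags)[flags[i, ]])
  }))
  if (is.null(reasons_long))
    reasons_long <- data.frame(id = character(), reason = character())
  excluded <- data.frame(
    id = as.character(records$id[drop]),
    reasons = vapply(which(drop), function(i)
      paste(colnames(flags)[flags[i, ]], collapse = ";"), character(1)))
  structure(list(kept = records[!drop, , drop = FALSE],
                 excluded = excluded,
                 reasons = reasons_long,
                 counts = colSums(flags),
                 stats = stats,
                 sd_rules_applied = sd_ok,
                 n_input = nrow(records)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Specimen QC report\n")
  cat(sprintf("  input records : %d\n", x$n_input))
  cat(sprintf("  kept          : %d\n", nrow(x$kept)))
  cat(sprintf("  excluded      : %d\n", nrow(x$excluded)))
  cat("  exclusions by rule (a record may trip several):\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-18s %d\n", nm, x$counts[[nm]]))
  if (!x$sd_rules_applied) cat("  [3-SD rules skipped: too few survivors]\n")
  invisible(x)
}

#' Per-record disposition table of a QC report
#'
#' One row per input record: id, kept flag, semicolon-joined reason codes.
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @return A data.frame suitable for [write_cohort()].
#' @export
as.data.frame.qc_report <- function(x, ...) {
  ids <- c(as.character(x$kept$id), x$excluded$id)
  data.frame(id = ids,
             kept = c(rep(TRUE, nrow(x$kept)),
                      rep(FALSE, nrow(x$excluded))),
             reasons = c(rep("", nrow(x$kept)), x$excluded$reasons))
}

#' Enrollment-flowchart retention summary
#'
#' @param report A `qc_report`, or the number of kept records.
#' @param initial_n Number initially enrolled (>= kept).
#' @return List with `excluded`, `kept`, and `kept_pct` (1 d.p.).
#' @examples
#' flowchart_counts(970, initial_n = 1287) # 75.4% retained
#' @export
flowchart_counts <- function(report, initial_n) {
  kept <- if (inherits(report, "qc_report")) nrow(report$kept) else report
  check_num(kept, "kept", 0)
  check_num(initial_n, "initial_n", 0)
  if (initial_n < kept)
    stop("initial_n is smaller than the number of kept records", call. = FALSE)
  list(excluded = initial_n - kept, kept = kept,
       kept_pct = round(100 * kept / initial_n, 1))
}
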