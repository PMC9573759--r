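#' Read a cohort file in the canonical delimited-text schema
#'
#' The canonical schema is comma-separated with a header row and columns
#' `id, sex {M,F}, age_y, height_cm, weight_kg, bmi, spot_na_mmol_l,
#' spot_k_mmol_l, spot_cr_mmol_l` plus, when 24 h collections are present,
#' `u24_vol_l, u24_na_mmol, u24_k_mmol, u24_cr_mmol, missed_l`. Missing
#' values are empty fields.
#'
#' @param path File path.
#' @param require_24h Require the 24 h-urine columns too?
#' @return A data.frame.
#' @export
read_cohort <- function(path, require_24h = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("id", "sex", "age_y", "spot_na_mmol_l", "spot_k_mmol_l",
            "spot_cr_mmol_l")
  if (require_24h)
    need <- c(need, "u24_vol_l", "u24_na_mmol", "u24_k_mmol", "u24_cr_mmol",
              "missed_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Write a cohort (or any tabular artifact) in the canonical schema
#'
#' @param df Data frame to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
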