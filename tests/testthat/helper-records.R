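# one fully populated record used across estimator oracle checks
full_record <- function() {
  data.frame(id = "R1", sex = "M", age_y = 65, height_cm = 165,
             weight_kg = 70, bmi = 70 / 1.65^2,
             spot_na_mmol_l = 130, spot_k_mmol_l = 55, spot_cr_mmol_l = 8.9,
             stringsAsFactors = FALSE)
}

# random paired series for agreement-metric property checks
random_pairs <- function(n, rho = 0.6, bias = 5, sd = 20) {
  x <- stats::rnorm(n, 180, 60)
  y <- bias + rho * (x - 180) + stats::rnorm(n, 0, sd) + 180
  list(measured = abs(x) + 1, estimated = y)
}
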