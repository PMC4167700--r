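# Shared fixtures: tiny CSVs and noise-free cohorts built in code.

write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

two_row_csv_lines <- c(
  "qt,rr,sex,age,manufacturer",
  "400,950,male,50,NK",
  "388,876,female,45,FD")

# exactly collinear power-law table: QT = scale * RR^alpha (seconds)
powerlaw_table <- function(alpha, rr = c(0.6, 0.8, 1.0, 1.2),
                           scale = 0.4) {
  interval_table(qt = scale * rr^alpha, rr = rr,
                 sex = rep(c("female", "male"), length.out = length(rr)),
                 age = seq(30, 60, length.out = length(rr)),
                 manufacturer = "X")
}

# zero-noise two-manufacturer cohort from the generator itself; with
# effects = FALSE the gender/age/device terms are zeroed too, making
# QT an exact function of RR alone
zero_noise_cohort <- function(mode = "log", n_total = 40, seed = 7,
                              effects = TRUE) {
  p <- default_params(paste0("combined_", mode))
  k <- if (effects) 1 else 0
  p2 <- cohort_params(mode = p$mode, strata = p$strata, slope = p$slope,
                      gender_effect = k * p$gender_effect,
                      age_effect = k * p$age_effect,
                      manufacturer_effect = k * p$manufacturer_effect,
                      intercept = p$intercept_resolved,
                      residual_sd = 0,
                      manufacturer_levels = p$manufacturer_levels)
  generate_cohort(scale_cohort(p2, n_total = n_total), seed = seed)
}

# independent OLS oracle: closed-form normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- stats::cor(x, y)^2
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# independent Fisher oracle: probability-mass two-sided rule via dhyper
fisher_oracle <- function(out_a, n_a, out_b, n_b) {
  k <- out_a + out_b
  support <- max(0, k - n_b):min(k, n_a)
  probs <- stats::dhyper(support, n_a, n_b, k)
  obs <- stats::dhyper(out_a, n_a, n_b, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
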