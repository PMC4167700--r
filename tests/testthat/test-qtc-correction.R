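test_that("named formulas reproduce hand-computed corrections", {
  expect_equal(compute_qtc(correction_model("bazett"), 0.400, 0.81),
               0.400 / 0.9, tolerance = 1e-12)
  expect_equal(compute_qtc(correction_model("fridericia"), 0.400, 0.729),
               0.400 / 0.9, tolerance = 1e-12)
  expect_equal(compute_qtc(correction_model("ecaps12"), 0.400, 0.9),
               0.400 + 0.1 / 7, tolerance = 1e-12)
  expect_equal(compute_qtc(correction_model("framingham"), 0.400, 0.9),
               0.400 + 0.154 * 0.1, tolerance = 1e-12)
  expect_equal(compute_qtc(correction_model("power", 0.347), 0.400, 0.9),
               0.400 * exp(-0.347 * log(0.9)), tolerance = 1e-12)
  expect_error(compute_qtc(correction_model("bazett"), -0.4, 0.9),
               "positive")
  expect_error(correction_model("bazett", 0.5), "no parameter")
  expect_error(correction_model("power"), "parameter")
})

test_that("every correction is anchored at RR = 1 s", {
  models <- c(lapply(c("bazett", "fridericia", "framingham", "ecaps12"),
                     correction_model),
              list(correction_model("power", 0.347),
                   correction_model("linear", 0.152)))
  set.seed(33)
  qt <- runif(200, 0.25, 0.55)
  for (m in models)
    expect_lt(max(abs(compute_qtc(m, qt, rep(1, 200)) - qt)), 1e-12)
})

test_that("power exponents reproduce Bazett and Fridericia exactly", {
  set.seed(34)
  qt <- runif(1000, 0.25, 0.55)
  rr <- runif(1000, 0.5, 1.5)
  expect_lt(max(abs(compute_qtc(correction_model("power", 0.5), qt, rr) -
                      compute_qtc(correction_model("bazett"), qt, rr))),
            1e-12)
  expect_lt(max(abs(compute_qtc(correction_model("power", 1 / 3), qt, rr) -
                      compute_qtc(correction_model("fridericia"), qt,
                                  rr))), 1e-12)
})

test_that("log and raw fits agree with the normal-equations oracle", {
  set.seed(35)
  for (i in seq_len(20)) {
    n <- sample(5:50, 1)
    tab <- interval_table(qt = runif(n, 0.3, 0.5),
                          rr = runif(n, 0.6, 1.4),
                          sex = sample(c("female", "male"), n, TRUE),
                          age = runif(n, 20, 80), manufacturer = "X")
    fl <- fit_log_correction(tab)
    ol <- ols_oracle(log(tab$rr), log(tab$qt))
    expect_equal(fl$slope, ol$slope, tolerance = 1e-10)
    expect_equal(fl$intercept, ol$intercept, tolerance = 1e-10)
    expect_equal(fl$r_squared, ol$r_squared, tolerance = 1e-10)
    fr <- fit_raw_correction(tab)
    or <- ols_oracle(tab$rr, tab$qt)
    expect_equal(fr$slope, or$slope, tolerance = 1e-10)
    expect_true(fr$ci["lower"] <= fr$slope && fr$slope <= fr$ci["upper"])
  }
})

test_that("noise-free data give exact slopes and R-squared 1", {
  tab <- powerlaw_table(0.347)
  fit <- fit_log_correction(tab)
  expect_equal(fit$slope, 0.347, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # two points plus their log-log midpoint: slope ln(0.5)/ln(0.25)
  rr <- c(1.0, 0.25, exp(mean(log(c(1, 0.25)))))
  qt <- 0.4 * rr^0.5
  tab2 <- interval_table(qt, rr, c("male", "female", "male"),
                         c(30, 40, 50), "X")
  expect_equal(fit_log_correction(tab2)$slope, 0.5, tolerance = 1e-12)

  lin <- interval_table(qt = 0.26 + 0.154 * c(0.6, 0.8, 1.0, 1.2),
                        rr = c(0.6, 0.8, 1.0, 1.2),
                        sex = c("male", "female", "male", "female"),
                        age = c(30, 40, 50, 60), manufacturer = "X")
  fr <- fit_raw_correction(lin)
  expect_equal(fr$slope, 0.154, tolerance = 1e-12)
  expect_equal(fr$r_squared, 1, tolerance = 1e-12)

  const <- interval_table(qt = c(0.4, 0.41, 0.42), rr = rep(0.9, 3),
                          sex = c("male", "female", "male"),
                          age = c(30, 40, 50), manufacturer = "X")
  expect_error(fit_raw_correction(const), "degenerate")
})

test_that("build_correction anchors fitted models at RR = 1", {
  tab <- powerlaw_table(0.347)
  m <- build_correction(fit_log_correction(tab))
  expect_equal(m$kind, "power")
  expect_equal(m$parameter, 0.347, tolerance = 1e-12)
  lin <- interval_table(qt = 0.25 + 0.152 * c(0.6, 0.9, 1.2),
                        rr = c(0.6, 0.9, 1.2),
                        sex = c("male", "female", "male"),
                        age = c(30, 40, 50), manufacturer = "X")
  ml <- build_correction(fit_raw_correction(lin))
  expect_equal(ml$kind, "linear")
  expect_equal(ml$parameter, 0.152, tolerance = 1e-12)
  # slope 0 -> identity correction
  id <- correction_model("linear", 0)
  expect_equal(compute_qtc(id, 0.4, 0.7), 0.4)
})

test_that("residual beta obeys the analytic law alpha - gamma", {
  for (alpha in c(0.30, 0.347, 0.40)) {
    tab <- powerlaw_table(alpha, rr = seq(0.5, 1.5, length.out = 9))
    for (gamma in c(1 / 3, 0.347, 0.5)) {
      b <- residual_slope(tab, correction_model("power", gamma))$slope
      expect_equal(b, alpha - gamma, tolerance = 1e-10)
    }
  }
  # published-method signs on data with the fitted exponent: Bazett
  # over-corrects (negative beta), Fridericia slightly under (positive)
  tab <- powerlaw_table(0.347, rr = seq(0.5, 1.5, length.out = 9))
  expect_equal(residual_slope(tab, correction_model("bazett"))$slope,
               -0.153, tolerance = 1e-10)
  expect_equal(residual_slope(tab, correction_model("fridericia"))$slope,
               0.347 - 1 / 3, tolerance = 1e-10)
  expect_equal(residual_slope(tab, correction_model("power", 0.347))$slope,
               0, tolerance = 1e-10)
})

test_that("fitted slope recovers the generating exponent on preset data", {
  tab <- generate_cohort(scale_cohort(default_params("fukuda_log"),
                                      n_total = 10000), seed = 1)
  fit <- fit_log_correction(tab)
  expect_lt(abs(fit$slope - 0.347), 0.01)
  tabr <- generate_cohort(scale_cohort(default_params("fukuda_raw"),
                                       n_total = 10000), seed = 1)
  fitr <- fit_raw_correction(tabr)
  expect_lt(abs(fitr$slope - 0.156), 0.005)
})
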