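test_that("pooled-variance t test matches hand computation", {
  same <- student_t_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  r <- student_t_compare(c(1, 2, 3), c(4, 5, 6))
  # pooled SD = 1, so t = -3 / sqrt(2/3)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(r$t, 4), tolerance = 1e-10)
  expect_equal(r$difference, -3)
  expect_error(student_t_compare(1, c(1, 2)), "at least 2")
  # |t| grows with mean separation at fixed SD and n
  r2 <- student_t_compare(c(1, 2, 3), c(7, 8, 9))
  expect_gt(abs(r2$t), abs(r$t))
})

test_that("Fisher exact outlier test matches the dhyper oracle and is
           symmetric", {
  cases <- list(c(275, 42673, 36, 8631), c(145, 30081, 9, 1898),
                c(5, 100, 5, 100), c(0, 50, 3, 60))
  for (cs in cases) {
    p <- fisher_exact_outliers(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
    expect_equal(p, fisher_exact_outliers(cs[3], cs[4], cs[1], cs[2]),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact_outliers(5, 100, 5, 100), 1)
  expect_error(fisher_exact_outliers(10, 5, 1, 100), "counts")
})

test_that("multivariable fit recovers constructed coefficients exactly", {
  set.seed(50)
  n <- 400
  rr <- runif(n, 0.6, 1.4)
  male <- rep(c(1, 0), n / 2)
  age <- runif(n, 20, 80)
  dev <- rep(c(0, 1), each = n / 2)
  qt <- exp(-0.95 + 0.347 * log(rr) - 0.0123 * male + 0.000686 * age +
              0.0275 * dev)
  tab <- interval_table(qt, rr, ifelse(male == 1, "male", "female"),
                        age, ifelse(dev == 1, "NK", "FD"),
                        manufacturer_levels = c("FD", "NK"))
  fit <- fit_multivariate(tab, "log")
  expect_equal(coef_of(fit, "rr"), 0.347, tolerance = 1e-9)
  expect_equal(coef_of(fit, "gender_male"), -0.0123, tolerance = 1e-9)
  expect_equal(coef_of(fit, "age"), 0.000686, tolerance = 1e-9)
  expect_equal(coef_of(fit, "manufacturer"), 0.0275, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # every CI contains its estimate
  expect_true(all(fit$coefficients$ci_lower <= fit$coefficients$estimate &
                    fit$coefficients$estimate <= fit$coefficients$ci_upper))
  expect_error(fit_multivariate(tab[tab$sex == "male", ], "log"),
               "sex")
})

test_that("combined presets recover the published device coefficients", {
  tab <- generate_cohort(scale_cohort(default_params("combined_raw"),
                                      n_total = 20000), seed = 13)
  fit <- fit_multivariate(tab, "raw")
  expect_lt(abs(coef_of(fit, "manufacturer") - 10.610), 1.0)
  tabl <- generate_cohort(scale_cohort(default_params("combined_log"),
                                       n_total = 20000), seed = 13)
  fitl <- fit_multivariate(tabl, "log")
  expect_lt(abs(coef_of(fitl, "gender_male") - (-0.0123)), 0.003)
  expect_lt(abs(coef_of(fitl, "manufacturer") - 0.0275), 0.003)
})

test_that("log-coefficient back-transform is multiplicative", {
  expect_equal(implied_qt_difference(0, 400), 0)
  expect_equal(implied_qt_difference(0.0275, 400),
               400 * (exp(0.0275) - 1), tolerance = 1e-12)
  expect_equal(implied_qt_difference(log(2), 400), 400)
  # applying c then -c returns to the start
  b <- 400
  up <- b + implied_qt_difference(0.1, b)
  expect_equal(up + implied_qt_difference(-0.1, up), b, tolerance = 1e-9)
})

test_that("age-adjusted RR offset matches exact constructions", {
  n <- 200
  age <- seq(25, 75, length.out = n)
  rr_fd <- 0.860 + 0 * age
  rr_nk <- rr_fd + 0.08495
  tab <- interval_table(qt = rep(0.4, 2 * n), rr = c(rr_fd, rr_nk),
                        sex = "male", age = c(age, age),
                        manufacturer = rep(c("FD", "NK"), each = n),
                        manufacturer_levels = c("FD", "NK"))
  r <- adjusted_rr_difference(tab, "male")
  expect_equal(r$coefficient_ms, 84.95, tolerance = 1e-9)
  expect_equal(r$percent, 100 * 84.95 / 860, tolerance = 1e-9)
  # zero offset -> zero coefficient and percent
  tab0 <- interval_table(qt = rep(0.4, 2 * n), rr = c(rr_fd, rr_fd),
                         sex = "male", age = c(age, age),
                         manufacturer = rep(c("FD", "NK"), each = n),
                         manufacturer_levels = c("FD", "NK"))
  r0 <- adjusted_rr_difference(tab0, "male")
  expect_equal(r0$coefficient_ms, 0, tolerance = 1e-9)
  expect_equal(r0$percent, 0, tolerance = 1e-9)
  expect_error(adjusted_rr_difference(tab[tab$manufacturer == "FD", ],
                                      "male"), "single-manufacturer")
})

test_that("synthetic males reproduce the stratum-mean RR gap", {
  tab <- generate_cohort(scale_cohort(default_params("combined_raw"),
                                      n_total = 20000), seed = 17)
  r <- adjusted_rr_difference(tab, "male")
  # generator has no age-RR link, so the adjusted offset is the
  # difference of stratum means, 947.6 - 859.7 = 87.9 ms
  expect_lt(abs(r$coefficient_ms - 87.9), 5)
})

test_that("log transforms are flagged closer to Gaussian on skewed data", {
  set.seed(60)
  n <- 10000
  tab <- generate_cohort(scale_cohort(default_params("nihon_log"),
                                      n_total = n), seed = 61)
  d <- distribution_diagnostics(tab)
  flags <- attr(d, "log_closer")
  expect_true(flags[["rr"]])  # RR is lognormal by construction
  # an exactly lognormal variable: log reduces skewness
  x <- exp(rnorm(n, 0, 0.3))
  tab2 <- interval_table(qt = x, rr = exp(rnorm(n, 0, 0.2)),
                         sex = sample(c("female", "male"), n, TRUE),
                         age = runif(n, 20, 80), manufacturer = "X")
  d2 <- distribution_diagnostics(tab2)
  sk <- setNames(d2$skewness, d2$variable)
  expect_lt(abs(sk[["log_qt"]]), abs(sk[["qt"]]))
  # a normal sample has near-zero skewness
  expect_lt(abs(sk[["log_rr"]]), 0.1)
})

test_that("preset cohorts separate manufacturers decisively in t tests", {
  tab <- generate_cohort(default_params("combined_log"), seed = 19)
  males <- tab[tab$sex == "male", ]
  a <- males$qt[males$manufacturer == "FukudaDenshi"]
  b <- males$qt[males$manufacturer == "NihonKohden"]
  r <- student_t_compare(a, b)
  expect_lt(r$p_value, 2.2e-16)
  expect_lt(r$difference, 0)  # second device measures longer QT
})
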