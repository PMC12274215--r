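test_that("synthetic bundles are complete, valid, grid-conformant and seed-deterministic", {
  ref <- generate_reference(seed = 42)
  expect_length(ref$curves, 18L)
  expect_identical(nrow(validate_reference(ref)), 0L)

  # grid layout: 6-month steps to age 4, then annual (25 nodes for the
  # birth-to-20 parameters); annual grids elsewhere
  expect_identical(reference_grid("height"),
                   c(seq(0, 4, by = 0.5), seq(5, 20, by = 1)))
  for (p in c("height", "weight", "bmi", "head_circumference")) {
    expect_identical(nrow(get_curve(ref, p, "male")$nodes), 25L)
  }
  expect_identical(nrow(get_curve(ref, "sitting_height", "female")$nodes), 19L)
  expect_identical(nrow(get_curve(ref, "foot_length", "male")$nodes), 18L)

  # smooth monotone-increasing medians for size parameters
  for (p in c("height", "weight", "head_circumference", "arm_span",
              "sitting_height", "leg_length", "foot_length")) {
    expect_true(all(diff(get_curve(ref, p, "female")$nodes$M) > 0))
  }
  # identity-mode parameters tabulate L = 1 everywhere
  expect_true(all(get_curve(ref, "height", "male")$nodes$L == 1))
  # skewed parameters carry a negative Box-Cox power
  expect_true(all(get_curve(ref, "weight", "male")$nodes$L < 0))

  # byte-equal serialization for a repeated seed; different seed differs
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_reference(generate_reference(seed = 42), f1)
  write_reference(generate_reference(seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  write_reference(generate_reference(seed = 43), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_reference(seed = 5))
  invisible(generate_cohort(generate_reference(seed = 5), n = 3, seed = 6))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("synthetic cohorts carry exact ground truth, off-grid ages and extremes", {
  ref <- generate_reference(seed = 2)
  co <- generate_cohort(ref, n = 30, seed = 11)
  expect_length(co$records, 30L)
  expect_setequal(unique(co$truth$sex), c("male", "female"))

  # both on-grid and off-grid ages occur
  heights <- co$truth[co$truth$parameter == "height", ]
  on_grid <- heights$age_years %in% reference_grid("height")
  expect_true(any(on_grid) && any(!on_grid))

  # each parameter probes both percentile extremes
  for (p in parameter_order) {
    zs <- co$truth$true_z[co$truth$parameter == p]
    expect_true(any(zs == 4) && any(zs == -4))
  }

  # every observation respects its parameter's age domain
  reg <- default_registry()
  dom <- reg[match(co$truth$parameter, reg$parameter), ]
  expect_true(all(dom$age_min <= co$truth$age_years &
                    co$truth$age_years <= dom$age_max))

  # determinism
  co2 <- generate_cohort(ref, n = 30, seed = 11)
  expect_identical(co$truth, co2$truth)
})

test_that("the engine recovers generating z exactly, including fixed-z cohorts", {
  ref <- generate_reference(seed = 8)
  # fixed z0 = 0: every value sits on the median curve
  co0 <- generate_cohort(ref, n = 10, seed = 3, z_dist = "fixed", z0 = 0,
                         extremes = FALSE)
  for (i in seq_len(nrow(co0$truth))) {
    z <- evaluate_measurement(ref, co0$truth$parameter[i], co0$truth$sex[i],
                              co0$truth$age_years[i], co0$truth$value[i])$z
    expect_equal(z, 0, tolerance = 1e-9)
  }
  # ground-truth recovery across fixed z levels
  for (z0 in c(-3, -1, 1, 3)) {
    co <- generate_cohort(ref, n = 6, seed = 4, z_dist = "fixed", z0 = z0,
                          extremes = FALSE)
    zs <- vapply(seq_len(nrow(co$truth)), function(i) {
      evaluate_measurement(ref, co$truth$parameter[i], co$truth$sex[i],
                           co$truth$age_years[i], co$truth$value[i])$z
    }, numeric(1))
    expect_equal(zs, rep(z0, length(zs)), tolerance = 1e-9)
  }
  # standard-normal cohort: empirical mean of recovered z within the CLT
  # bound 3/sqrt(N) of zero
  con <- generate_cohort(ref, n = 30, seed = 12, extremes = FALSE)
  zs <- vapply(seq_len(nrow(con$truth)), function(i) {
    evaluate_measurement(ref, con$truth$parameter[i], con$truth$sex[i],
                         con$truth$age_years[i], con$truth$value[i])$z
  }, numeric(1))
  expect_equal(zs, con$truth$true_z, tolerance = 1e-9)
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)))
})

test_that("engine and manual oracle disagree when one side is perturbed", {
  ref <- generate_reference(seed = 6)
  co <- generate_cohort(ref, n = 8, seed = 7)
  ac <- agreement_check(ref, co, tol = 1e-9)
  expect_equal(ac$rate, 100)
  expect_identical(ac$n_total, nrow(co$truth))

  # a constant +0.2 shift on one side breaks every pair
  cmp <- ac$comparisons
  expect_true(all(abs(cmp$z_engine - (cmp$z_oracle + 0.2)) > 1e-9))

  # zero tolerance against itself still agrees (same code path both sides)
  self_rate <- 100 * mean(abs(cmp$z_oracle - cmp$z_oracle) <= 0)
  expect_identical(self_rate, 100)
})

test_that("rater-study simulation schedules 54 calculations per rater", {
  ref <- generate_reference(seed = 1)
  s <- simulate_rater_study(ref, n_raters = 10, n_cases = 3,
                            manual_error_sd = 0.2, seed = 5)
  expect_identical(nrow(s), 540L)  # 10 raters x 54 calculations
  per_rater <- table(s$rater_id)
  expect_true(all(per_rater == 54L))
  expect_identical(sum(s$method == "manual"), 270L)
  expect_identical(sum(s$method == "smart"), 270L)
  expect_true(all(s$deviation >= 0 & is.finite(s$deviation)))
  # the automated method reproduces the gold standard exactly
  expect_true(all(s$deviation[s$method == "smart"] == 0))
  # determinism
  expect_identical(s, simulate_rater_study(ref, n_raters = 10, n_cases = 3,
                                           manual_error_sd = 0.2, seed = 5))
  # zero reading error: all deviations vanish
  s0 <- simulate_rater_study(ref, n_raters = 2, n_cases = 3,
                             manual_error_sd = 0, seed = 5)
  expect_true(all(s0$deviation == 0))
})

test_that("manual deviations converge to the half-normal median", {
  ref <- generate_reference(seed = 1)
  s <- simulate_rater_study(ref, n_raters = 60, n_cases = 3,
                            manual_error_sd = 0.2, seed = 17)
  med <- median(s$deviation[s$method == "manual"])
  # frozen closed form: 0.2 * sqrt(2) * erfinv(1/2) = 0.134898
  expect_equal(med, 0.1348980, tolerance = 0.1)
})

test_that("deviation summaries use linear-interpolation quantiles and report-style layout", {
  s <- data.frame(rater_id = 1L, case_id = 1L, parameter = "height",
                  method = "manual", deviation = c(0.1, 0.2, 0.3))
  sm <- summarize_deviations(s, "method")
  expect_identical(sm$median, 0.2)
  expect_identical(sm$n, 3L)

  s2 <- s
  s2$deviation <- c(0.07, 0.17, 0.30)
  sm2 <- summarize_deviations(s2, "method")
  expect_equal(c(sm2$iqr_low, sm2$median, sm2$iqr_high), c(0.12, 0.17, 0.235))

  zeros <- s
  zeros$method <- "smart"
  zeros$deviation <- 0
  smz <- summarize_deviations(zeros, "method")
  expect_identical(c(smz$median, smz$iqr_low, smz$iqr_high), c(0, 0, 0))

  expect_error(summarize_deviations(s[0, ], "method"),
               class = "agrowth_domain_error")
  expect_error(summarize_deviations(s, "nonexistent"),
               class = "agrowth_domain_error")

  # table layout: one row per rater plus "all", per-case and total columns
  ref <- generate_reference(seed = 1)
  full <- simulate_rater_study(ref, n_raters = 4, n_cases = 3, seed = 2)
  tab <- deviation_table(full)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$rater[5], "all")
  expect_identical(ncol(tab), 1L + 3L * 2L + 2L)
  expect_match(tab$total_smart, "^0\\.00 \\[0\\.00-0\\.00\\]$")
})
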