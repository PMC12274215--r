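test_that("identity z-score is the plain standardisation", {
  nd <- lms_node(5, 1, 86, 3)
  expect_identical(zscore_identity(86, nd), 0)
  expect_identical(zscore_identity(89, nd), 1)
  expect_identical(zscore_identity(92, nd), 2)
  expect_error(zscore_identity(90, list(M = 86, S = 0)),
               class = "agrowth_coefficient_error")
})

test_that("Box-Cox z-score follows Cole's form with a stable log limit", {
  # definitional zero at the median, any L
  for (L in c(-2, -0.5, 0, 1, 2.3)) {
    nd <- lms_node(6, L, 16, 0.11)
    expect_equal(zscore_boxcox(16, nd), 0)
  }
  # frozen high-precision evaluation of ((12/16)^-1.5 - 1)/(-1.5 * 0.11)
  expect_equal(zscore_boxcox(12, lms_node(6, -1.5, 16, 0.11)),
               -3.27030738084244, tolerance = 1e-12)
  # L = 1 coincides with (X - M)/(M*S)
  nd1 <- lms_node(6, 1, 16, 0.11)
  expect_equal(zscore_boxcox(18, nd1), (18 - 16) / (16 * 0.11))
  # log-limit: X = M*e^S at L ~ 0 gives z = 1
  ndS <- lms_node(6, 1e-9, 16, 0.11)
  expect_equal(zscore_boxcox(16 * exp(0.11), ndS), 1, tolerance = 1e-6)
  expect_error(zscore_boxcox(-1, nd1), class = "agrowth_domain_error")
  expect_error(zscore_boxcox(12, list(L = 1, M = 16, S = -0.1)),
               class = "agrowth_coefficient_error")
})

test_that("Box-Cox transform is continuous in L near zero", {
  x <- 13.2; M <- 16; S <- 0.11
  limit <- log(x / M) / S
  for (eps in c(1e-4, 1e-6)) {
    for (sgn in c(-1, 1)) {
      z <- zscore_boxcox(x, lms_node(6, sgn * eps, M, S))
      expect_lt(abs(z - limit), 10 * eps)
    }
  }
})

test_that("percentile conversion matches numerical integration of the normal density", {
  expect_identical(percentile_from_z(0), 50)
  # independent oracle: adaptive quadrature of the density
  cdf_quad <- function(z) {
    stats::integrate(stats::dnorm, -Inf, z, rel.tol = 1e-12)$value
  }
  for (z in seq(-6, 6, by = 0.75)) {
    expect_equal(percentile_from_z(z), 100 * cdf_quad(z), tolerance = 1e-7)
  }
  expect_equal(percentile_from_z(1.959964), 97.5, tolerance = 1e-3)
  expect_error(percentile_from_z(Inf), class = "agrowth_domain_error")
  expect_error(percentile_from_z(NA_real_), class = "agrowth_domain_error")
})

test_that("percentiles are symmetric, bounded, and invertible", {
  zs <- seq(-6, 6, by = 0.25)
  p <- percentile_from_z(zs)
  expect_true(all(p > 0 & p < 100))
  expect_true(all(diff(p) > 0))
  expect_equal(p + percentile_from_z(-zs), rep(100, length(zs)),
               tolerance = 1e-10)
  # round trips
  expect_identical(z_from_percentile(50), 0)
  expect_equal(z_from_percentile(percentile_from_z(1.3)), 1.3,
               tolerance = 1e-9)
  expect_equal(percentile_from_z(z_from_percentile(2.5)), 2.5,
               tolerance = 1e-9)
  expect_equal(z_from_percentile(2.5), -1.959964, tolerance = 1e-3)
  expect_error(z_from_percentile(0), class = "agrowth_domain_error")
  expect_error(z_from_percentile(100), class = "agrowth_domain_error")
})

test_that("inverse transform recovers measurements in both modes", {
  ndi <- lms_node(5, 1, 86, 3)
  expect_identical(measurement_from_z(0, ndi, "identity"), 86)
  expect_identical(measurement_from_z(2, ndi, "identity"), 92)
  ndb <- lms_node(6, -1.2, 16, 0.11)
  expect_identical(measurement_from_z(0, ndb, "boxcox"), 16)
  # frozen high-precision evaluation of 16*(1 - 1.2*0.11*1.5)^(1/-1.2)
  expect_equal(measurement_from_z(1.5, ndb, "boxcox"), 19.2297959432603,
               tolerance = 1e-12)
  # inverse consistency across modes, L values and z range
  for (L in c(-1.4, -0.3, 0, 0.5, 1)) {
    nd <- lms_node(6, L, 16, 0.11)
    for (z in c(-3, -1, -1e-4, 0, 0.7, 2.5)) {
      x <- measurement_from_z(z, nd, "boxcox")
      expect_equal(zscore_boxcox(x, nd), z, tolerance = 1e-9)
    }
  }
  for (z in c(-4, -0.5, 0, 1.2, 4)) {
    x <- measurement_from_z(z, ndi, "identity")
    expect_equal(zscore_identity(x, ndi), z, tolerance = 1e-9)
  }
  # beyond the Box-Cox support
  expect_error(measurement_from_z(8, lms_node(6, -1.4, 16, 0.15), "boxcox"),
               class = "agrowth_invertibility_error")
})

test_that("z is strictly increasing in the measurement in both modes", {
  xs <- seq(8, 30, by = 0.5)
  ndb <- lms_node(6, -1.3, 16, 0.12)
  zb <- vapply(xs, zscore_boxcox, numeric(1), node = ndb)
  expect_true(all(diff(zb) > 0))
  ndi <- lms_node(5, 1, 86, 3)
  zi <- vapply(seq(60, 110, by = 1), zscore_identity, numeric(1), node = ndi)
  expect_true(all(diff(zi) > 0))
})

test_that("derived measures follow their standard definitions", {
  expect_identical(derive_bmi(16, 100), 16)
  expect_identical(derive_bmi(20, 100), 20)
  expect_equal(derive_bmi(18.5, 95), 20.4986149584488, tolerance = 1e-12)
  expect_error(derive_bmi(0, 100), class = "agrowth_domain_error")

  pr <- derive_proportions(100, 60)
  expect_identical(pr$leg_length, 40)
  expect_identical(pr$relative_sitting_height, 60)
  expect_identical(derive_proportions(120, 60)$relative_sitting_height, 50)
  pr2 <- derive_proportions(113.4, 66.3)
  expect_equal(pr2$leg_length, 47.1)
  expect_equal(pr2$relative_sitting_height, 58.4656084656085,
               tolerance = 1e-12)
  expect_error(derive_proportions(100, 100), class = "agrowth_domain_error")
})

test_that("decimal age is days since birth over 365.25", {
  expect_equal(decimal_age("2010-01-01", "2020-01-01"), 3652 / 365.25)
  expect_error(decimal_age("2020-01-01", "2010-01-01"),
               class = "agrowth_domain_error")
  expect_error(decimal_age("not-a-date", "2020-01-01"),
               class = "agrowth_domain_error")
})

test_that("evaluate_measurement composes interpolation, transform and percentile", {
  ref <- generate_reference(seed = 3)
  cv <- get_curve(ref, "height", "male")
  a <- cv$nodes$age_years[10]
  m <- cv$nodes$M[10]

  # at a grid age with X = M: z = 0, percentile = 50, no interpolation flag
  r <- evaluate_measurement(ref, "height", "male", a, m)
  expect_equal(r$z, 0)
  expect_equal(r$percentile, 50)
  expect_false("interpolated_age" %in% r$flags)

  # off-grid age sets the flag
  r2 <- evaluate_measurement(ref, "height", "male", a + 0.21, m)
  expect_true("interpolated_age" %in% r2$flags)

  # |z| > 3 sets the extreme flag
  r3 <- evaluate_measurement(ref, "height", "male", a,
                             m + 3.5 * cv$nodes$S[10])
  expect_true("extreme_percentile" %in% r3$flags)

  # equals the manual two-step pipeline for both modes
  set.seed(21)
  for (p in c("height", "weight", "bmi", "foot_length")) {
    spec <- parameter_spec(p)
    for (i in 1:5) {
      age <- runif(1, spec$age_min, spec$age_max)
      node <- interpolate_lms(get_curve(ref, p, "female"), age)
      x <- measurement_from_z(runif(1, -2, 2), node, spec$mode)
      r <- evaluate_measurement(ref, p, "female", age, x)
      z_manual <- if (spec$mode == "boxcox") zscore_boxcox(x, node)
                  else zscore_identity(x, node)
      expect_identical(r$z, z_manual)
      expect_identical(r$percentile, percentile_from_z(z_manual))
      expect_identical(r$lms_used$M, node$M)
    }
  }

  expect_error(evaluate_measurement(ref, "height", "male", 21, 130),
               class = "agrowth_domain_error")
  ref$curves[["arm_span:male"]] <- NULL
  expect_error(evaluate_measurement(ref, "arm_span", "male", 10, 80),
               "arm_span", class = "agrowth_lookup_error")
})
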