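# LMS engine: forward/inverse z-score transforms, percentile conversion,
# derived anthropometric measures, and single-measurement evaluation.

# Below this |L| the Box-Cox transform switches to its analytic log limit
# to avoid catastrophic cancellation; relative error of the limit is O(L).
L_EPS <- 1e-7

check_node_coefs <- function(node, need_M_positive = TRUE) {
  if (!is.finite(node$S) || node$S <= 0) {
    agrowth_error("invalid LMS coefficients: S must be > 0",
                  "agrowth_coefficient_error")
  }
  if (need_M_positive && (!is.finite(node$M) || node$M <= 0)) {
    agrowth_error("invalid LMS coefficients: M must be > 0",
                  "agrowth_coefficient_error")
  }
  invisible(node)
}

#' z-score for identity-mode (L = 1) parameters
#'
#' The standard score Z = (X - M)/S, used for the seven parameters whose
#' reference charts tabulate L = 1 (height, head circumference, sitting
#' height, leg length, arm span, relative sitting height, foot length).
#' Here S is an absolute standard deviation in measurement units.
#'
#' @param x Measured value, in parameter units.
#' @param node An `lms_node` (or list with `M` and `S`).
#' @return The z-score, dimensionless.
#' @export
#' @examples
#' zscore_identity(92, lms_node(5, 1, 86, 3))  # 2
zscore_identity <- function(x, node) {
  check_node_coefs(node, need_M_positive = FALSE)
  (x - node$M) / node$S
}

#' z-score via the full Box-Cox LMS transform
#'
#' Cole's LMS form Z = ((X/M)^L - 1) / (L * S), used for weight and BMI,
#' whose reference distributions are skewed. For |L| below `1e-7` the
#' analytic limit Z = ln(X/M)/S is used. Here S is a coefficient of
#' variation (dimensionless).
#'
#' @param x Measured value, must be > 0.
#' @param node An `lms_node` with M > 0, S > 0.
#' @return The z-score, dimensionless.
#' @export
#' @examples
#' zscore_boxcox(12, lms_node(6, -1.5, 16, 0.11))
zscore_boxcox <- function(x, node) {
  check_node_coefs(node)
  if (!is.finite(x) || x <= 0) {
    agrowth_error("measurement must be > 0 for the Box-Cox transform",
                  "agrowth_domain_error")
  }
  if (abs(node$L) < L_EPS) {
    log(x / node$M) / node$S
  } else {
    ((x / node$M)^node$L - 1) / (node$L * node$S)
  }
}

#' Convert a z-score to a percentile
#'
#' 100 times the standard normal CDF; strictly increasing in z.
#'
#' @param z Finite z-score.
#' @return Percentile in (0, 100).
#' @export
percentile_from_z <- function(z) {
  if (!is.numeric(z) || anyNA(z) || any(!is.finite(z))) {
    agrowth_error("z must be finite", "agrowth_domain_error")
  }
  100 * stats::pnorm(z)
}

#' Convert a percentile to a z-score
#'
#' Inverse of [percentile_from_z()] via the standard normal quantile
#' function.
#'
#' @param p Percentile, strictly between 0 and 100.
#' @return The z-score.
#' @export
z_from_percentile <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 100)) {
    agrowth_error("percentile must lie strictly between 0 and 100",
                  "agrowth_domain_error")
  }
  stats::qnorm(p / 100)
}

#' Invert a z-score back to a measurement value
#'
#' The inverse LMS transform, used to draw centile curves and to generate
#' synthetic measurements with known true z. Identity mode: X = M + z*S.
#' Box-Cox mode: X = M * (1 + L*S*z)^(1/L), with the log-limit
#' X = M * exp(S*z) for |L| < 1e-7. In Box-Cox mode, z values with
#' 1 + L*S*z <= 0 lie outside the transform's support and raise an
#' invertibility error.
#'
#' @param z z-score.
#' @param node An `lms_node`.
#' @param mode `"identity"` or `"boxcox"`.
#' @return The measurement value X such that the forward transform of X
#'   returns `z`.
#' @export
#' @examples
#' measurement_from_z(2, lms_node(5, 1, 86, 3), "identity")  # 92
measurement_from_z <- function(z, node, mode = c("identity", "boxcox")) {
  mode <- match.arg(mode)
  check_node_coefs(node, need_M_positive = (mode == "boxcox"))
  if (!is.finite(z)) {
    agrowth_error("z must be finite", "agrowth_domain_error")
  }
  if (mode == "identity") {
    return(node$M + z * node$S)
  }
  if (abs(node$L) < L_EPS) {
    return(node$M * exp(node$S * z))
  }
  base <- 1 + node$L * node$S * z
  if (base <= 0) {
    agrowth_error(sprintf(
      "z = %s is beyond the Box-Cox transform's support (1 + L*S*z = %s <= 0)",
      format(z), format(base)),
      "agrowth_invertibility_error")
  }
  node$M * base^(1 / node$L)
}

#' Body mass index from weight and height
#'
#' @param weight Weight in kg, > 0.
#' @param height Height in cm, > 0.
#' @return BMI in kg/m^2.
#' @export
derive_bmi <- function(weight, height) {
  if (!is.finite(weight) || weight <= 0 || !is.finite(height) || height <= 0) {
    agrowth_error("weight and height must be positive", "agrowth_domain_error")
  }
  weight / (height / 100)^2
}

#' Body proportions from height and sitting height
#'
#' Subischial leg length (standing height minus sitting height) and
#' relative sitting height (sitting height as a percentage of standing
#' height) — the proportion indices central to disproportionate short
#' stature.
#'
#' @param height Standing height in cm.
#' @param sitting_height Sitting height in cm, with
#'   0 < sitting_height < height.
#' @return List with `leg_length` (cm) and `relative_sitting_height` (%).
#' @export
derive_proportions <- function(height, sitting_height) {
  if (!is.finite(height) || !is.finite(sitting_height) ||
      sitting_height <= 0 || height <= 0) {
    agrowth_error("height and sitting height must be positive",
                  "agrowth_domain_error")
  }
  if (sitting_height >= height) {
    agrowth_error("sitting height must be strictly less than height",
                  "agrowth_domain_error")
  }
  list(leg_length = height - sitting_height,
       relative_sitting_height = 100 * sitting_height / height)
}

#' Decimal age from birth and visit dates
#'
#' Conventional decimal age: (visit - birth) in days divided by 365.25.
#'
#' @param birth_date,visit_date `Date`s or ISO-8601 strings.
#' @return Age in decimal years.
#' @export
decimal_age <- function(birth_date, visit_date) {
  to_date <- function(x) {
    tryCatch(as.Date(x), error = function(e) as.Date(NA))
  }
  b <- to_date(birth_date)
  v <- to_date(visit_date)
  if (anyNA(b) || anyNA(v)) {
    agrowth_error("dates must be valid ISO-8601 (YYYY-MM-DD)",
                  "agrowth_domain_error")
  }
  if (any(v < b)) {
    agrowth_error("visit date precedes birth date", "agrowth_domain_error")
  }
  as.numeric(v - b) / 365.25
}

#' Evaluate one measurement against a reference set
#'
#' The core single-observation pipeline: interpolates L/M/S at the
#' patient's age, dispatches on the parameter's transformation mode
#' (identity vs Box-Cox), and returns the z-score, percentile, the
#' coefficients actually applied, and informational flags
#' (`interpolated_age` when the age is not a grid node;
#' `extreme_percentile` when |z| > 3; `derived_input` is attached by the
#' patient pipeline for computed inputs like BMI).
#'
#' @param ref A `reference_set`.
#' @param parameter Parameter identifier (see [parameter_order]).
#' @param sex `"male"` or `"female"`.
#' @param age Age in decimal years, within the parameter's domain.
#' @param value Measured value X in parameter units.
#' @return A list of class `zscore_result` with fields `parameter`, `sex`,
#'   `age`, `value`, `z`, `percentile`, `lms_used`, `flags`.
#' @export
evaluate_measurement <- function(ref, parameter, sex, age, value) {
  spec <- parameter_spec(parameter)
  curve <- get_curve(ref, parameter, sex)
  node <- interpolate_lms(curve, age)
  z <- if (spec$mode == "boxcox") zscore_boxcox(value, node)
       else zscore_identity(value, node)
  flags <- character()
  if (is.na(match(age, curve$nodes$age_years))) flags <- c(flags, "interpolated_age")
  if (abs(z) > 3) flags <- c(flags, "extreme_percentile")
  structure(list(parameter = parameter, sex = sex, age = age, value = value,
                 z = z, percentile = percentile_from_z(z),
                 lms_used = node, flags = flags),
            class = "zscore_result")
}

#' @export
print.zscore_result <- function(x, ...) {
  cat(sprintf("%s (%s, age %.2f y): value %.4g -> z = %.2f, percentile = %.1f%s\n",
              x$parameter, x$sex, x$age, x$value, x$z, x$percentile,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]")
              else ""))
  invisible(x)
}
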