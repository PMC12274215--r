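# Parameter registry: the nine anthropometric parameters the tool evaluates,
# their units, valid age domains and LMS transformation mode.

#' Canonical parameter order
#'
#' Registry order used for all deterministic output ordering (reports, batch
#' files, centile tables).
#'
#' @format Character vector of the nine parameter identifiers.
#' @export
parameter_order <- c(
  "height", "weight", "bmi", "head_circumference",
  "sitting_height", "leg_length", "arm_span",
  "relative_sitting_height", "foot_length"
)

#' Default anthropometric parameter registry
#'
#' Returns the registry of the nine parameters supported by the growth
#' assessment engine. Height, weight, BMI and head circumference are defined
#' from birth to 20 years; sitting height, leg length, arm span and relative
#' sitting height from 2 to 20 years; foot length from 3 to 20 years.
#' Weight and BMI use the full Box-Cox LMS transform (`mode = "boxcox"`,
#' S is a coefficient of variation); the remaining seven parameters have
#' L = 1 in their source charts and use the plain standardisation
#' Z = (X - M)/S with S an absolute standard deviation (`mode = "identity"`).
#'
#' @return A data frame with columns `parameter`, `units`, `age_min`,
#'   `age_max`, `mode`, one row per parameter, in canonical order.
#' @export
#' @examples
#' default_registry()
default_registry <- function() {
  data.frame(
    parameter = parameter_order,
    units = c("cm", "kg", "kg/m2", "cm", "cm", "cm", "cm", "%", "cm"),
    age_min = c(0, 0, 0, 0, 2, 2, 2, 2, 3),
    age_max = rep(20, 9L),
    mode = c("identity", "boxcox", "boxcox", "identity", "identity",
             "identity", "identity", "identity", "identity"),
    stringsAsFactors = FALSE
  )
}

#' Look up one parameter's registry entry
#'
#' @param parameter One of the nine parameter identifiers (see
#'   [parameter_order]).
#' @return A one-row data frame with the registry fields for `parameter`.
#' @export
#' @examples
#' parameter_spec("foot_length")$age_min  # 3
parameter_spec <- function(parameter) {
  reg <- default_registry()
  i <- match(parameter, reg$parameter)
  if (is.na(i)) {
    agrowth_error(
      sprintf("unknown parameter '%s' (known: %s)",
              parameter, paste(reg$parameter, collapse = ", ")),
      "agrowth_lookup_error"
    )
  }
  reg[i, , drop = FALSE]
}

# Classed error helper so callers can test on condition class.
agrowth_error <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "agrowth_error"),
                      call = call))
}
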