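# Synthetic fixtures: seeded LMS reference bundles emulating the structure
# of the European achondroplasia charts (whose coefficients are not
# redistributable here), synthetic patient cohorts with known true z, the
# engine-vs-oracle agreement check, and a desk-scale replica of the
# inter-rater reliability study design.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Reference age grid for one parameter
#'
#' Birth-to-20 parameters (height, weight, BMI, head circumference) use
#' 6-month intervals up to age 4 years and 1-year intervals thereafter
#' (25 nodes); the remaining parameters use annual nodes over their
#' domains (2-20 or 3-20 years).
#'
#' @param parameter Parameter identifier.
#' @return Numeric vector of node ages in years.
#' @export
reference_grid <- function(parameter) {
  spec <- parameter_spec(parameter)
  if (spec$age_min == 0) c(seq(0, 4, by = 0.5), seq(5, 20, by = 1))
  else seq(spec$age_min, spec$age_max, by = 1)
}

# Curve-shape controls per parameter: median at domain start and at 20 y
# (per sex), saturating-growth curvature, S range over the domain, and the
# Box-Cox power range for skewed parameters. Magnitudes emulate
# achondroplasia anthropometry (short stature, macrocephaly, high relative
# sitting height); they are synthetic stand-ins, not published coefficients.
synthetic_shapes <- function() {
  list(
    height                  = list(m0 = c(male = 47.5, female = 46.5),
                                   m20 = c(male = 131, female = 124),
                                   k = 2.6, s = c(1.8, 5.2), L = NULL),
    weight                  = list(m0 = c(male = 3.4, female = 3.2),
                                   m20 = c(male = 56, female = 51),
                                   k = 0.9, s = c(0.11, 0.15),
                                   L = c(-0.6, -1.3)),
    bmi                     = list(m0 = c(male = 15.5, female = 15.2),
                                   m20 = c(male = 31, female = 30),
                                   k = 0.7, s = c(0.10, 0.15),
                                   L = c(-0.8, -1.4)),
    head_circumference      = list(m0 = c(male = 37.5, female = 36.8),
                                   m20 = c(male = 58.5, female = 57.3),
                                   k = 5.0, s = c(1.2, 1.7), L = NULL),
    sitting_height          = list(m0 = c(male = 46, female = 45),
                                   m20 = c(male = 88, female = 83),
                                   k = 1.6, s = c(1.6, 3.4), L = NULL),
    leg_length              = list(m0 = c(male = 19, female = 18.5),
                                   m20 = c(male = 44, female = 41.5),
                                   k = 1.4, s = c(1.2, 3.0), L = NULL),
    arm_span                = list(m0 = c(male = 56, female = 54.5),
                                   m20 = c(male = 112, female = 105),
                                   k = 1.8, s = c(2.0, 5.0), L = NULL),
    relative_sitting_height = list(m0 = c(male = 69.5, female = 69.0),
                                   m20 = c(male = 66.5, female = 66.0),
                                   k = 1.2, s = c(1.8, 2.3), L = NULL),
    foot_length             = list(m0 = c(male = 13.5, female = 13.2),
                                   m20 = c(male = 22.5, female = 21),
                                   k = 1.5, s = c(0.7, 1.1), L = NULL)
  )
}

#' Generate a synthetic LMS reference bundle
#'
#' Deterministically builds a complete 18-curve bundle (9 parameters x 2
#' sexes) on the standard age grids. Medians follow a smooth saturating
#' curve between domain-start and age-20 anchors; S varies smoothly over
#' the domain with a small seeded jitter; Box-Cox parameters get a
#' smoothly varying negative L (right-skewed weight and BMI) with seeded
#' jitter. The result always passes [validate_reference()] with zero
#' violations and is byte-identical for a fixed seed.
#'
#' @param seed Integer seed.
#' @param source,version Metadata labels.
#' @return A `reference_set` of 18 curves.
#' @export
#' @examples
#' ref <- generate_reference(seed = 42)
#' nrow(get_curve(ref, "height", "male")$nodes)  # 25
generate_reference <- function(seed = 1L, source = "synthetic-achondroplasia",
                               version = "1") {
  shapes <- synthetic_shapes()
  with_seed(seed, {
    curves <- list()
    for (p in parameter_order) {
      sh <- shapes[[p]]
      ages <- reference_grid(p)
      t <- (ages - ages[1]) / (ages[length(ages)] - ages[1])
      sat <- (1 - exp(-sh$k * t)) / (1 - exp(-sh$k))
      for (sx in c("male", "female")) {
        M <- sh$m0[[sx]] + (sh$m20[[sx]] - sh$m0[[sx]]) * sat
        S <- sh$s[1] + (sh$s[2] - sh$s[1]) * t
        S <- S * exp(stats::runif(length(ages), -0.02, 0.02))
        if (is.null(sh$L)) {
          L <- rep(1, length(ages))
        } else {
          L <- sh$L[1] + (sh$L[2] - sh$L[1]) * t +
            stats::runif(length(ages), -0.02, 0.02)
        }
        if (any(M <= 0) || any(S <= 0)) {
          agrowth_error("shape controls imply non-positive M or S",
                        "agrowth_config_error")
        }
        curves[[length(curves) + 1L]] <-
          reference_curve(p, sx, data.frame(age_years = ages, L = L,
                                            M = M, S = S))
      }
    }
    reference_set(curves, metadata = list(source = source, version = version))
  })
}

#' Generate a synthetic patient cohort with known true z
#'
#' Samples `n` patients across both sexes and the pediatric age range,
#' with stratified ages: alternating patients sit exactly on grid nodes
#' and strictly between nodes, so interpolation is exercised. Every
#' parameter whose age domain contains the patient's age receives a
#' measurement produced by the inverse LMS transform at a known true z.
#' True z values are drawn standard-normal, truncated at |z| = 4 so that
#' Box-Cox observations stay within the transform's support (or held at
#' `z0` when `z_dist = "fixed"`); with `extremes = TRUE`, each parameter
#' additionally gets one z = +4 and one z = -4 observation to probe the
#' percentile boundaries.
#'
#' @param ref A `reference_set`.
#' @param n Number of patients, >= 1.
#' @param seed Integer seed.
#' @param z_dist `"normal"` or `"fixed"`.
#' @param z0 True z used for every measurement when `z_dist = "fixed"`.
#' @param extremes Inject |z| = 4 observations per parameter?
#' @return A list of class `synthetic_cohort` with `records` (list of
#'   `patient_record`) and `truth` (data frame: patient_id, sex,
#'   age_years, parameter, value, true_z).
#' @export
generate_cohort <- function(ref, n = 30L, seed = 1L,
                            z_dist = c("normal", "fixed"), z0 = 0,
                            extremes = TRUE) {
  z_dist <- match.arg(z_dist)
  stopifnot(n >= 1)
  reg <- default_registry()
  with_seed(seed, {
    sexes <- rep(c("male", "female"), length.out = n)
    on_grid_pool <- c(seq(0, 4, by = 0.5), seq(5, 20, by = 1))
    ages <- numeric(n)
    for (i in seq_len(n)) {
      if (i %% 2L == 1L) {
        ages[i] <- sample(on_grid_pool, 1L)
      } else {
        # strictly between annual grid nodes for every parameter
        ages[i] <- sample(0:19, 1L) + stats::runif(1L, 0.05, 0.45)
        if (abs(ages[i] %% 0.5) < 0.01) ages[i] <- ages[i] + 0.013
      }
    }
    truth <- list()
    add_obs <- function(i, p, z) {
      spec <- reg[reg$parameter == p, ]
      node <- interpolate_lms(get_curve(ref, p, sexes[i]), ages[i])
      x <- measurement_from_z(z, node, spec$mode)
      data.frame(patient_id = sprintf("synth%03d", i), sex = sexes[i],
                 age_years = ages[i], parameter = p, value = x,
                 true_z = z, stringsAsFactors = FALSE)
    }
    for (i in seq_len(n)) {
      for (p in reg$parameter[reg$age_min <= ages[i] & ages[i] <= reg$age_max]) {
        # truncate at |z| = 4 so Box-Cox observations stay invertible
        z <- if (z_dist == "fixed") z0 else max(-4, min(4, stats::rnorm(1L)))
        truth[[length(truth) + 1L]] <- add_obs(i, p, z)
      }
    }
    truth <- do.call(rbind, truth)
    if (extremes) {
      for (p in reg$parameter) {
        spec <- reg[reg$parameter == p, ]
        eligible <- which(spec$age_min <= ages & ages <= spec$age_max)
        for (k in seq_len(min(2L, length(eligible)))) {
          i <- eligible[k]
          zx <- c(4, -4)[k]
          sel <- truth$patient_id == sprintf("synth%03d", i) &
            truth$parameter == p
          truth[sel, c("value", "true_z")] <-
            add_obs(i, p, zx)[, c("value", "true_z")]
        }
      }
    }
    rownames(truth) <- NULL
    key <- factor(truth$patient_id, levels = unique(truth$patient_id))
    records <- lapply(split(seq_len(nrow(truth)), key), function(idx) {
      sub <- truth[idx, , drop = FALSE]
      patient_record(sub$patient_id[1L], sub$sex[1L], sub$age_years[1L],
                     stats::setNames(sub$value, sub$parameter))
    })
    structure(list(records = unname(records), truth = truth),
              class = "synthetic_cohort")
  })
}

#' Engine-vs-oracle agreement check
#'
#' Scores every measurement of a cohort twice: with the engine
#' ([evaluate_measurement()]) and with the implementation-independent
#' step-by-step oracle ([manual_zscore()]), and reports the percentage of
#' pairs agreeing within `tol`. Because the two paths share no
#' interpolation or transform code, 100% agreement is evidence of
#' correctness rather than self-comparison.
#'
#' @param ref A `reference_set`.
#' @param cohort A `synthetic_cohort` (or any data frame shaped like its
#'   `truth` component).
#' @param tol Absolute z-score tolerance for a match.
#' @return List of class `agreement_result`: `rate` (percent in [0, 100]),
#'   `n_total`, `n_match`, and `comparisons` (per-pair data frame with
#'   engine and oracle z).
#' @export
agreement_check <- function(ref, cohort, tol = 1e-9) {
  truth <- if (inherits(cohort, "synthetic_cohort")) cohort$truth else cohort
  flat <- as.data.frame(ref)
  z_engine <- numeric(nrow(truth))
  z_oracle <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    z_engine[i] <- evaluate_measurement(ref, truth$parameter[i], truth$sex[i],
                                        truth$age_years[i], truth$value[i])$z
    z_oracle[i] <- manual_zscore(flat, truth$parameter[i], truth$sex[i],
                                 truth$age_years[i], truth$value[i])
  }
  match_ok <- abs(z_engine - z_oracle) <= tol
  cmp <- data.frame(truth[, c("patient_id", "sex", "age_years", "parameter")],
                    z_engine = z_engine, z_oracle = z_oracle,
                    match = match_ok)
  structure(list(rate = 100 * mean(match_ok), n_total = nrow(truth),
                 n_match = sum(match_ok), comparisons = cmp),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement: %.1f%% (%d/%d z-score pairs within tolerance)\n",
              x$rate, x$n_match, x$n_total))
  invisible(x)
}

#' Simulate the inter-rater reliability study design
#'
#' Replicates, at desk scale, a reliability assessment in which each of
#' `n_raters` raters scores `n_cases` patients on all nine parameters by
#' two methods — manual chart reading and the automated tool — i.e.
#' `n_cases * 9 * 2` calculations per rater (54 for the standard 3-case
#' design). The gold standard is the engine itself; manual absolute
#' deviations are modelled as |N(0, manual_error_sd)| chart-reading noise
#' (a documented stand-in, not a reproduction of human data), and
#' automated deviations are exactly 0 (the tool reproduces the gold
#' standard by construction; set `smart_digits` to model read-off
#' rounding).
#'
#' @param ref A `reference_set`.
#' @param n_raters Number of raters.
#' @param n_cases Number of patient cases.
#' @param manual_error_sd SD of the zero-mean normal chart-reading error,
#'   in z units, >= 0.
#' @param seed Integer seed.
#' @param smart_digits Optional decimal places at which the automated
#'   method's z is read off; `NULL` means exact.
#' @return Data frame of deviation samples: `rater_id`, `case_id`,
#'   `parameter`, `method` (`"manual"`/`"smart"`), `deviation` (absolute
#'   z-score deviation from gold standard, >= 0).
#' @export
simulate_rater_study <- function(ref, n_raters = 10L, n_cases = 3L,
                                 manual_error_sd = 0.2, seed = 1L,
                                 smart_digits = NULL) {
  stopifnot(manual_error_sd >= 0, n_raters >= 1, n_cases >= 1)
  with_seed(seed, {
    # cases old enough that all nine parameters are in domain
    case_ages <- stats::runif(n_cases, 3, 20)
    case_sex <- rep(c("male", "female"), length.out = n_cases)
    gold <- list()
    for (ci in seq_len(n_cases)) {
      for (p in parameter_order) {
        spec <- parameter_spec(p)
        node <- interpolate_lms(get_curve(ref, p, case_sex[ci]), case_ages[ci])
        zt <- max(-3, min(3, stats::rnorm(1L, 0, 1.5)))
        x <- measurement_from_z(zt, node, spec$mode)
        gold[[length(gold) + 1L]] <- data.frame(
          case_id = ci, parameter = p,
          z_gold = evaluate_measurement(ref, p, case_sex[ci], case_ages[ci], x)$z,
          stringsAsFactors = FALSE)
      }
    }
    gold <- do.call(rbind, gold)
    out <- list()
    for (ri in seq_len(n_raters)) {
      for (gi in seq_len(nrow(gold))) {
        manual_dev <- abs(stats::rnorm(1L, 0, manual_error_sd))
        smart_dev <- if (is.null(smart_digits)) 0 else
          abs(round(gold$z_gold[gi], smart_digits) - gold$z_gold[gi])
        out[[length(out) + 1L]] <- data.frame(
          rater_id = ri, case_id = gold$case_id[gi],
          parameter = gold$parameter[gi],
          method = c("manual", "smart"),
          deviation = c(manual_dev, smart_dev), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Summarize absolute z-score deviations
#'
#' Median and interquartile bounds per group, using linear interpolation
#' between order statistics (quantile type 7, the mainstream default).
#'
#' @param samples Deviation samples as returned by
#'   [simulate_rater_study()].
#' @param group_by Character vector of grouping columns (any of
#'   `rater_id`, `case_id`, `parameter`, `method`).
#' @return Data frame with the grouping columns plus `median`, `iqr_low`,
#'   `iqr_high`, `n`.
#' @export
summarize_deviations <- function(samples, group_by = "method") {
  if (!nrow(samples)) {
    agrowth_error("no deviation samples to summarize", "agrowth_domain_error")
  }
  missing_cols <- setdiff(group_by, names(samples))
  if (length(missing_cols)) {
    agrowth_error(sprintf("unknown grouping column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "agrowth_domain_error")
  }
  key <- interaction(samples[group_by], drop = TRUE, lex.order = TRUE,
                     sep = "\r")
  parts <- split(seq_len(nrow(samples)), key)
  out <- do.call(rbind, lapply(parts, function(idx) {
    q <- stats::quantile(samples$deviation[idx], c(0.25, 0.5, 0.75),
                         type = 7, names = FALSE)
    cbind(samples[idx[1L], group_by, drop = FALSE],
          data.frame(median = q[2L], iqr_low = q[1L], iqr_high = q[3L],
                     n = length(idx)))
  }))
  rownames(out) <- NULL
  out
}

#' Deviation table in reliability-report layout
#'
#' Formats deviation samples as one row per rater plus an `"all"` row, and
#' one `median [iqr_low-iqr_high]` column per (case, method) plus total
#' columns per method.
#'
#' @inheritParams summarize_deviations
#' @param digits Decimal places in the formatted cells.
#' @return Data frame of formatted character cells.
#' @export
deviation_table <- function(samples, digits = 2) {
  fmt <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%.*f [%.*f-%.*f]", digits, q[2], digits, q[1], digits, q[3])
  }
  raters <- sort(unique(samples$rater_id))
  cases <- sort(unique(samples$case_id))
  rows <- lapply(c(as.list(raters), list(raters)), function(rs) {
    sub <- samples[samples$rater_id %in% rs, ]
    cells <- list(rater = if (length(rs) > 1L) "all" else as.character(rs))
    for (ci in cases) {
      for (m in c("manual", "smart")) {
        cells[[sprintf("case%d_%s", ci, m)]] <-
          fmt(sub$deviation[sub$case_id == ci & sub$method == m])
      }
    }
    for (m in c("manual", "smart")) {
      cells[[paste0("total_", m)]] <- fmt(sub$deviation[sub$method == m])
    }
    as.data.frame(cells, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
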