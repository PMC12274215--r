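# Patient pipeline: reading measurement files, per-patient assessment with
# derivation of BMI and body proportions, batch CSV processing, and
# centile-curve tables.

patient_csv_columns <- c("patient_id", "sex", "age_years", "parameter", "value")

#' Construct a patient record
#'
#' @param patient_id Opaque identifier.
#' @param sex `"male"` or `"female"`.
#' @param age Decimal age in years; alternatively supply `birth_date` and
#'   `visit_date` (ISO-8601), converted via [decimal_age()].
#' @param measurements Named numeric vector mapping parameter identifiers
#'   to measured values (any non-empty subset of the nine parameters).
#' @param birth_date,visit_date Optional dates used when `age` is missing.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(patient_id, sex, age = NULL, measurements,
                           birth_date = NULL, visit_date = NULL) {
  if (is.null(age)) {
    if (is.null(birth_date) || is.null(visit_date)) {
      agrowth_error("supply either age or both birth_date and visit_date",
                    "agrowth_record_error")
    }
    age <- decimal_age(birth_date, visit_date)
  }
  if (!is.numeric(age) || !is.finite(age) || age < 0) {
    agrowth_error(sprintf("unresolvable age for patient '%s'", patient_id),
                  "agrowth_record_error")
  }
  if (!length(sex) || !sex %in% c("male", "female")) {
    agrowth_error(sprintf("unresolvable sex for patient '%s'", patient_id),
                  "agrowth_record_error")
  }
  m <- unlist(measurements)
  if (!length(m) || is.null(names(m)) || any(names(m) == "")) {
    agrowth_error("at least one named measurement is required",
                  "agrowth_record_error")
  }
  structure(list(patient_id = as.character(patient_id), sex = sex,
                 age = as.numeric(age), measurements = m),
            class = "patient_record")
}

#' Read a patient measurement CSV
#'
#' Long layout (exact header `patient_id,sex,age_years,parameter,value`,
#' one measurement per row) or wide layout (one column per parameter,
#' melted to long form). When the long file carries `birth_date` and
#' `visit_date` columns instead of `age_years`, ages are derived via
#' [decimal_age()].
#'
#' @param path CSV path.
#' @param format `"long"` (default) or `"wide"`.
#' @return Data frame in long layout with the standard columns, plus a
#'   `line` column giving the source line number of each row.
#' @export
read_patients <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    agrowth_error(sprintf("patient file not found: %s", path),
                  "agrowth_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  if (format == "wide") {
    id_cols <- intersect(c("patient_id", "sex", "age_years",
                           "birth_date", "visit_date"), names(df))
    par_cols <- intersect(parameter_order, names(df))
    if (!length(par_cols)) {
      agrowth_error("wide patient CSV has no parameter columns",
                    "agrowth_schema_error")
    }
    long <- do.call(rbind, lapply(par_cols, function(p) {
      sub <- df[df[[p]] != "" & !is.na(df[[p]]), c(id_cols, "line", p),
                drop = FALSE]
      if (!nrow(sub)) return(NULL)
      sub$parameter <- p
      names(sub)[names(sub) == p] <- "value"
      sub
    }))
    df <- long[order(long$line), , drop = FALSE]
  }
  if (!"age_years" %in% names(df) &&
      all(c("birth_date", "visit_date") %in% names(df))) {
    df$age_years <- vapply(seq_len(nrow(df)), function(i) {
      tryCatch(decimal_age(df$birth_date[i], df$visit_date[i]),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  missing_cols <- setdiff(patient_csv_columns, names(df))
  if (length(missing_cols)) {
    agrowth_error(sprintf("patient CSV is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "agrowth_schema_error")
  }
  rownames(df) <- NULL
  df[, c(patient_csv_columns, "line")]
}

# Split a long patient table into patient_record objects, isolating
# malformed rows instead of aborting. Returns list(records, bad_rows).
collect_records <- function(df) {
  bad <- list()
  keep <- rep(TRUE, nrow(df))
  age_num <- suppressWarnings(as.numeric(df$age_years))
  val_num <- suppressWarnings(as.numeric(df$value))
  for (i in seq_len(nrow(df))) {
    msg <- NULL
    if (!df$parameter[i] %in% parameter_order) {
      msg <- sprintf("unknown parameter '%s'", df$parameter[i])
    } else if (!df$sex[i] %in% c("male", "female")) {
      msg <- sprintf("invalid sex '%s'", df$sex[i])
    } else if (is.na(age_num[i]) || age_num[i] < 0) {
      msg <- sprintf("invalid age '%s'", df$age_years[i])
    } else if (is.na(val_num[i])) {
      msg <- sprintf("non-numeric value '%s'", df$value[i])
    }
    if (!is.null(msg)) {
      keep[i] <- FALSE
      bad[[length(bad) + 1L]] <-
        data.frame(line = df$line[i], message = msg, stringsAsFactors = FALSE)
    }
  }
  df <- df[keep, , drop = FALSE]
  df$age_years <- age_num[keep]
  df$value <- val_num[keep]
  key <- paste(df$patient_id, df$sex, df$age_years, sep = "\r")
  records <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                    function(idx) {
    sub <- df[idx, , drop = FALSE]
    patient_record(sub$patient_id[1L], sub$sex[1L], sub$age_years[1L],
                   stats::setNames(sub$value, sub$parameter))
  })
  list(records = unname(records),
       bad_rows = if (length(bad)) do.call(rbind, bad)
                  else data.frame(line = integer(), message = character()))
}

#' Assess one patient against a reference set
#'
#' Evaluates every measured parameter (in canonical registry order) via
#' [evaluate_measurement()]. With `derive = TRUE`, BMI is computed from
#' weight and height, and leg length and relative sitting height from
#' height and sitting height, whenever the target parameter was not itself
#' measured — measured values always win over derived ones; derived rows
#' carry the `derived_input` flag. Out-of-domain ages and missing curves
#' become `skipped` entries with reasons rather than aborting the record.
#'
#' @param rec A `patient_record`.
#' @param ref A `reference_set`.
#' @param derive Derive BMI and body proportions when absent?
#' @return A list of class `assessment_report` with `patient_id`, `sex`,
#'   `age`, `rows` (data frame: parameter, value, L, M, S, z, percentile,
#'   flags) and `skipped` (data frame: parameter, reason).
#' @export
assess_patient <- function(rec, ref, derive = TRUE) {
  stopifnot(inherits(rec, "patient_record"))
  values <- rec$measurements
  derived <- character()
  if (derive) {
    if (!"bmi" %in% names(values) &&
        all(c("weight", "height") %in% names(values))) {
      values[["bmi"]] <- derive_bmi(values[["weight"]], values[["height"]])
      derived <- c(derived, "bmi")
    }
    if (all(c("height", "sitting_height") %in% names(values)) &&
        values[["sitting_height"]] < values[["height"]]) {
      pr <- derive_proportions(values[["height"]], values[["sitting_height"]])
      for (p in c("leg_length", "relative_sitting_height")) {
        if (!p %in% names(values)) {
          values[[p]] <- pr[[p]]
          derived <- c(derived, p)
        }
      }
    }
  }
  rows <- list()
  skipped <- list()
  for (p in intersect(parameter_order, names(values))) {
    res <- tryCatch(
      evaluate_measurement(ref, p, rec$sex, rec$age, values[[p]]),
      agrowth_domain_error = function(e) conditionMessage(e),
      agrowth_lookup_error = function(e) conditionMessage(e),
      agrowth_coefficient_error = function(e) conditionMessage(e),
      agrowth_invertibility_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(parameter = p, reason = res, stringsAsFactors = FALSE)
      next
    }
    flags <- res$flags
    if (p %in% derived) flags <- c(flags, "derived_input")
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, value = values[[p]],
      L = res$lms_used$L, M = res$lms_used$M, S = res$lms_used$S,
      z = res$z, percentile = res$percentile,
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  empty_rows <- data.frame(parameter = character(), value = numeric(),
                           L = numeric(), M = numeric(), S = numeric(),
                           z = numeric(), percentile = numeric(),
                           flags = character(), stringsAsFactors = FALSE)
  structure(list(
    patient_id = rec$patient_id, sex = rec$sex, age = rec$age,
    rows = if (length(rows)) do.call(rbind, rows) else empty_rows,
    skipped = if (length(skipped)) do.call(rbind, skipped)
              else data.frame(parameter = character(), reason = character(),
                              stringsAsFactors = FALSE)),
    class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(sprintf("Assessment: patient %s (%s, age %.2f y)\n",
              x$patient_id, x$sex, x$age))
  if (nrow(x$rows)) {
    df <- x$rows
    df$z <- sprintf("%.2f", df$z)
    df$percentile <- sprintf("%.1f", df$percentile)
    print(df[, c("parameter", "value", "z", "percentile", "flags")],
          row.names = FALSE)
  }
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    for (i in seq_len(nrow(x$skipped))) {
      cat(sprintf("  %s: %s\n", x$skipped$parameter[i], x$skipped$reason[i]))
    }
  }
  invisible(x)
}

#' Batch-evaluate a patient measurement CSV
#'
#' Reads a long-format patient CSV, assesses every record, and writes one
#' output row per evaluated (patient, parameter) with the interpolated
#' coefficients used (header
#' `patient_id,sex,age_years,parameter,value,L,M,S,z,percentile,flags`;
#' flags semicolon-joined). Row order is input order, then canonical
#' registry order within a patient. Malformed input rows are recorded in
#' the summary with their line number and processing continues.
#'
#' @param in_csv Input patient CSV path.
#' @param ref A `reference_set`.
#' @param out_csv Output CSV path.
#' @param derive Passed to [assess_patient()].
#' @return Run summary: list with `records_processed`, `rows_written`,
#'   `skipped` (data frame patient_id/parameter/reason), `bad_rows`
#'   (data frame line/message).
#' @export
batch_process <- function(in_csv, ref, out_csv, derive = TRUE) {
  df <- read_patients(in_csv)
  parsed <- collect_records(df)
  out <- list()
  skips <- list()
  for (rec in parsed$records) {
    rep <- assess_patient(rec, ref, derive = derive)
    if (nrow(rep$rows)) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(patient_id = rep$patient_id, sex = rep$sex,
                   age_years = rep$age, stringsAsFactors = FALSE),
        rep$rows)
    }
    if (nrow(rep$skipped)) {
      skips[[length(skips) + 1L]] <- cbind(
        data.frame(patient_id = rep$patient_id, stringsAsFactors = FALSE),
        rep$skipped)
    }
  }
  out_df <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), sex = character(),
               age_years = numeric(), parameter = character(),
               value = numeric(), L = numeric(), M = numeric(), S = numeric(),
               z = numeric(), percentile = numeric(), flags = character())
  rownames(out_df) <- NULL
  utils::write.csv(out_df, out_csv, row.names = FALSE, quote = FALSE)
  list(records_processed = length(parsed$records),
       rows_written = nrow(out_df),
       skipped = if (length(skips)) do.call(rbind, skips)
                 else data.frame(patient_id = character(),
                                 parameter = character(),
                                 reason = character()),
       bad_rows = parsed$bad_rows)
}

#' Centile-curve table for one parameter
#'
#' Tabulates, over an age grid, the measurement values corresponding to
#' requested percentiles — the chart lines read in a manual workflow.
#' Each cell is `measurement_from_z(z_from_percentile(p))` at the
#' interpolated coefficients for that age. Grid ranges extending beyond
#' the parameter's age domain are truncated to it with a warning.
#'
#' @param ref A `reference_set`.
#' @param parameter Parameter identifier.
#' @param sex `"male"` or `"female"`.
#' @param percentiles Numeric vector strictly between 0 and 100.
#' @param age_step Grid step in years, > 0.
#' @param age_min,age_max Optional grid range (defaults to the parameter's
#'   domain).
#' @return Data frame with column `age_years` and one column `p<percentile>`
#'   per requested percentile, rows ordered by age.
#' @export
centile_table <- function(ref, parameter, sex,
                          percentiles = c(3, 10, 25, 50, 75, 90, 97),
                          age_step = 0.5, age_min = NULL, age_max = NULL) {
  if (any(percentiles <= 0) || any(percentiles >= 100)) {
    agrowth_error("percentiles must lie strictly between 0 and 100",
                  "agrowth_domain_error")
  }
  if (!is.numeric(age_step) || age_step <= 0) {
    agrowth_error("age_step must be > 0", "agrowth_domain_error")
  }
  spec <- parameter_spec(parameter)
  curve <- get_curve(ref, parameter, sex)
  lo <- age_min %||% spec$age_min
  hi <- age_max %||% spec$age_max
  if (lo < spec$age_min || hi > spec$age_max) {
    warning(sprintf("age grid truncated to [%s, %s] for %s",
                    format(spec$age_min), format(spec$age_max), parameter))
    lo <- max(lo, spec$age_min)
    hi <- min(hi, spec$age_max)
  }
  ages <- seq(lo, hi, by = age_step)
  zs <- z_from_percentile(percentiles)
  tab <- data.frame(age_years = ages)
  for (j in seq_along(percentiles)) {
    tab[[paste0("p", format(percentiles[j], trim = TRUE))]] <-
      vapply(ages, function(a) {
        measurement_from_z(zs[j], interpolate_lms(curve, a), spec$mode)
      }, numeric(1))
  }
  tab
}
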