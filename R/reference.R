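# Reference model: LMS reference bundles (curves of (age, L, M, S) nodes
# per parameter and sex), readers/writers, validation, and age interpolation.

curve_key <- function(parameter, sex) paste(parameter, sex, sep = ":")

#' Construct an LMS node
#'
#' One reference-grid entry: an age (decimal years) plus the LMS triplet.
#' L is the Box-Cox power (dimensionless), M the median in parameter units,
#' S the scale (coefficient of variation for Box-Cox parameters, absolute
#' standard deviation for identity-mode parameters).
#'
#' @param age Age in decimal years, finite and non-negative.
#' @param L,M,S LMS coefficients; M and S must be positive.
#' @return A list of class `lms_node` with fields `age`, `L`, `M`, `S`.
#' @export
lms_node <- function(age, L, M, S) {
  for (v in list(age = age, L = L, M = M, S = S)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      agrowth_error("LMS node fields must be finite numeric scalars",
                    "agrowth_validation_error")
    }
  }
  if (age < 0) agrowth_error("node age must be non-negative",
                             "agrowth_validation_error")
  if (M <= 0) agrowth_error("node M must be > 0", "agrowth_validation_error")
  if (S <= 0) agrowth_error("node S must be > 0", "agrowth_validation_error")
  structure(list(age = age, L = L, M = M, S = S), class = "lms_node")
}

#' Construct a reference curve
#'
#' Ordered LMS nodes for one (parameter, sex) pair. The constructor checks
#' only structural shape; full invariant checking (ordering, domain
#' coverage, positivity, identity-mode L) is done by [validate_reference()],
#' so that invalid curves can be represented and reported on.
#'
#' @param parameter Parameter identifier.
#' @param sex `"male"` or `"female"`.
#' @param nodes Data frame with columns `age_years`, `L`, `M`, `S`.
#' @return An object of class `reference_curve`.
#' @export
reference_curve <- function(parameter, sex, nodes) {
  stopifnot(is.character(parameter), length(parameter) == 1L)
  if (!sex %in% c("male", "female")) {
    agrowth_error(sprintf("sex must be 'male' or 'female', got '%s'", sex),
                  "agrowth_validation_error")
  }
  required <- c("age_years", "L", "M", "S")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    agrowth_error(sprintf("curve nodes lack column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "agrowth_schema_error")
  }
  nodes <- as.data.frame(nodes)[, required]
  rownames(nodes) <- NULL
  structure(list(parameter = parameter, sex = sex, nodes = nodes),
            class = "reference_curve")
}

#' Construct a reference set
#'
#' A collection of reference curves keyed by (parameter, sex), plus source
#' metadata. Duplicate (parameter, sex) keys are rejected.
#'
#' @param curves List of `reference_curve` objects.
#' @param metadata List with elements `source` and `version` (character).
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(curves, metadata = list(source = "unspecified",
                                                  version = "0")) {
  stopifnot(is.list(curves))
  keys <- vapply(curves, function(cv) curve_key(cv$parameter, cv$sex), "")
  if (anyDuplicated(keys)) {
    agrowth_error(sprintf("duplicate (parameter, sex) curve(s): %s",
                          paste(unique(keys[duplicated(keys)]), collapse = ", ")),
                  "agrowth_validation_error")
  }
  names(curves) <- keys
  structure(list(curves = curves,
                 metadata = list(source = as.character(metadata$source %||% "unspecified"),
                                 version = as.character(metadata$version %||% "0"))),
            class = "reference_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retrieve one curve from a reference set
#'
#' @param ref A `reference_set`.
#' @inheritParams reference_curve
#' @return The `reference_curve` for (parameter, sex).
#' @export
get_curve <- function(ref, parameter, sex) {
  cv <- ref$curves[[curve_key(parameter, sex)]]
  if (is.null(cv)) {
    agrowth_error(sprintf("no reference curve for parameter '%s', sex '%s'",
                          parameter, sex),
                  "agrowth_lookup_error")
  }
  cv
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("LMS reference set: %d curve(s) [source: %s, version: %s]\n",
              length(x$curves), x$metadata$source, x$metadata$version))
  for (cv in x$curves) {
    cat(sprintf("  %-24s %-6s %2d nodes, ages %.1f-%.1f\n",
                cv$parameter, cv$sex, nrow(cv$nodes),
                min(cv$nodes$age_years), max(cv$nodes$age_years)))
  }
  invisible(x)
}

#' Flatten a reference set to the long CSV layout
#'
#' @param x A `reference_set`.
#' @param ... Unused.
#' @return Data frame with columns `parameter,sex,age_years,L,M,S`, one row
#'   per node, curves in insertion order.
#' @export
as.data.frame.reference_set <- function(x, ...) {
  out <- do.call(rbind, lapply(x$curves, function(cv) {
    cbind(data.frame(parameter = cv$parameter, sex = cv$sex,
                     stringsAsFactors = FALSE),
          cv$nodes)
  }))
  rownames(out) <- NULL
  out
}

reference_csv_columns <- c("parameter", "sex", "age_years", "L", "M", "S")

#' Load an LMS reference bundle
#'
#' Reads a reference bundle from CSV (long layout, exact header
#' `parameter,sex,age_years,L,M,S`) or JSON
#' (`{metadata:{source,version}, curves:[{parameter, sex, nodes:[...]}]}`),
#' and validates it. Any invariant violation (non-increasing ages,
#' non-positive M or S, duplicate nodes, identity-mode L != 1, domain
#' mismatch) aborts the load with a message naming the offending
#' curve/node; duplicated (parameter, sex, age) rows are an error, never
#' deduplicated.
#'
#' @param path Path to the bundle file.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @return A validated `reference_set`.
#' @export
load_reference <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    agrowth_error(sprintf("reference file not found: %s", path),
                  "agrowth_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  ref <- if (format == "csv") read_reference_csv(path) else read_reference_json(path)
  viol <- validate_reference(ref)
  errs <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    agrowth_error(paste0("invalid reference bundle:\n",
                         paste(format_violations(errs), collapse = "\n")),
                  "agrowth_validation_error")
  }
  ref
}

read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(reference_csv_columns, names(df))
  if (length(missing_cols)) {
    agrowth_error(sprintf("reference CSV is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "agrowth_schema_error")
  }
  build_reference_from_long(df, metadata = list(source = basename(path),
                                                version = "0"))
}

read_reference_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$curves)) {
    agrowth_error("reference JSON is missing 'curves'", "agrowth_schema_error")
  }
  curves <- lapply(obj$curves, function(cu) {
    if (is.null(cu$parameter) || is.null(cu$sex) || is.null(cu$nodes)) {
      agrowth_error("each JSON curve needs 'parameter', 'sex' and 'nodes'",
                    "agrowth_schema_error")
    }
    nodes <- do.call(rbind, lapply(cu$nodes, function(nd) {
      for (f in c("age_years", "L", "M", "S")) {
        if (is.null(nd[[f]])) {
          agrowth_error(sprintf("JSON node in curve (%s, %s) is missing '%s'",
                                cu$parameter, cu$sex, f),
                        "agrowth_schema_error")
        }
      }
      data.frame(age_years = as.numeric(nd$age_years), L = as.numeric(nd$L),
                 M = as.numeric(nd$M), S = as.numeric(nd$S))
    }))
    reference_curve(cu$parameter, cu$sex, nodes)
  })
  md <- obj$metadata %||% list()
  check_duplicate_nodes(curves)
  reference_set(curves, metadata = list(source = md$source %||% "unspecified",
                                        version = md$version %||% "0"))
}

build_reference_from_long <- function(df, metadata) {
  for (col in c("age_years", "L", "M", "S")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]])) {
      agrowth_error(sprintf("non-numeric value in reference column '%s'", col),
                    "agrowth_schema_error")
    }
  }
  keys <- curve_key(df$parameter, df$sex)
  curves <- lapply(split(seq_len(nrow(df)), factor(keys, levels = unique(keys))),
                   function(idx) {
    sub <- df[idx, , drop = FALSE]
    reference_curve(sub$parameter[1L], sub$sex[1L],
                    sub[, c("age_years", "L", "M", "S")])
  })
  check_duplicate_nodes(curves)
  reference_set(unname(curves), metadata = metadata)
}

check_duplicate_nodes <- function(curves) {
  for (cv in curves) {
    dup <- cv$nodes$age_years[duplicated(cv$nodes$age_years)]
    if (length(dup)) {
      agrowth_error(sprintf(
        "duplicate (parameter, sex, age) rows for (%s, %s) at age(s) %s",
        cv$parameter, cv$sex, paste(unique(dup), collapse = ", ")),
        "agrowth_validation_error")
    }
  }
  invisible(curves)
}

#' Write an LMS reference bundle
#'
#' Inverse of [load_reference()]: CSV uses the long layout with the exact
#' header `parameter,sex,age_years,L,M,S`; JSON nests nodes per curve and
#' carries the metadata. `load_reference(write_reference(ref, f))`
#' round-trips to a value-equal set.
#'
#' @param ref A `reference_set`.
#' @param path Output path.
#' @param format `"auto"`, `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(ref), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    obj <- list(
      metadata = ref$metadata,
      curves = lapply(unname(ref$curves), function(cv) {
        list(parameter = cv$parameter, sex = cv$sex,
             nodes = lapply(seq_len(nrow(cv$nodes)), function(i) {
               as.list(cv$nodes[i, c("age_years", "L", "M", "S")])
             }))
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

violation <- function(curve, node, rule, message, severity = "error") {
  data.frame(curve = curve, node = node, rule = rule, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

format_violations <- function(v) {
  sprintf("[%s] %s (%s, node %s): %s", v$severity, v$rule, v$curve, v$node,
          v$message)
}

#' Validate a reference set
#'
#' Checks every curve invariant and returns violations as data, not
#' exceptions: at least two nodes per curve; strictly increasing, finite,
#' non-negative node ages; M > 0 and S > 0 at every node; for parameters in
#' the default registry, node ages spanning exactly [age_min, age_max];
#' L = 1 at every node of an identity-mode parameter. A curve whose
#' identity-mode S looks like a coefficient of variation (S < 0.5 while
#' M > 20) yields a `"warning"`-severity record, since the identity formula
#' expects S as an absolute standard deviation.
#'
#' @param ref A `reference_set`.
#' @return Data frame with columns `curve`, `node`, `rule`, `message`,
#'   `severity`; zero rows iff all invariants hold.
#' @export
validate_reference <- function(ref) {
  out <- list()
  reg <- default_registry()
  for (key in names(ref$curves)) {
    cv <- ref$curves[[key]]
    nd <- cv$nodes
    n <- nrow(nd)
    if (n < 2L) {
      out[[length(out) + 1L]] <-
        violation(key, "curve", "nodes/min_count",
                  sprintf("curve has %d node(s); at least 2 required", n))
      next
    }
    bad_age <- which(!is.finite(nd$age_years) | nd$age_years < 0)
    for (i in bad_age) {
      out[[length(out) + 1L]] <-
        violation(key, as.character(i), "node/age",
                  sprintf("age %s is not finite and non-negative",
                          format(nd$age_years[i])))
    }
    non_incr <- which(diff(nd$age_years) <= 0)
    for (i in non_incr) {
      out[[length(out) + 1L]] <-
        violation(key, as.character(i + 1L), "nodes/ordering",
                  sprintf("ages not strictly increasing at age %s (after %s)",
                          format(nd$age_years[i + 1L]), format(nd$age_years[i])))
    }
    for (i in which(!is.finite(nd$M) | nd$M <= 0)) {
      out[[length(out) + 1L]] <-
        violation(key, as.character(i), "node/M_positive",
                  sprintf("M = %s must be > 0 (age %s)",
                          format(nd$M[i]), format(nd$age_years[i])))
    }
    for (i in which(!is.finite(nd$S) | nd$S <= 0)) {
      out[[length(out) + 1L]] <-
        violation(key, as.character(i), "node/S_positive",
                  sprintf("S = %s must be > 0 (age %s)",
                          format(nd$S[i]), format(nd$age_years[i])))
    }
    for (i in which(!is.finite(nd$L))) {
      out[[length(out) + 1L]] <-
        violation(key, as.character(i), "node/L_finite", "L must be finite")
    }
    ri <- match(cv$parameter, reg$parameter)
    if (is.na(ri)) {
      out[[length(out) + 1L]] <-
        violation(key, "curve", "curve/unknown_parameter",
                  sprintf("parameter '%s' is not in the default registry",
                          cv$parameter))
    } else {
      spec <- reg[ri, ]
      if (!length(non_incr) && !length(bad_age)) {
        if (nd$age_years[1L] != spec$age_min || nd$age_years[n] != spec$age_max) {
          out[[length(out) + 1L]] <-
            violation(key, "curve", "curve/domain",
                      sprintf("node ages span [%s, %s]; expected [%s, %s]",
                              format(nd$age_years[1L]), format(nd$age_years[n]),
                              format(spec$age_min), format(spec$age_max)))
        }
      }
      if (spec$mode == "identity") {
        for (i in which(nd$L != 1)) {
          out[[length(out) + 1L]] <-
            violation(key, as.character(i), "curve/identity_L",
                      sprintf("identity-mode parameter has L = %s (must be 1) at age %s",
                              format(nd$L[i]), format(nd$age_years[i])))
        }
        cv_like <- which(is.finite(nd$S) & is.finite(nd$M) &
                           nd$S > 0 & nd$S < 0.5 & nd$M > 20)
        for (i in cv_like) {
          out[[length(out) + 1L]] <-
            violation(key, as.character(i), "curve/s_convention",
                      sprintf("S = %s with M = %s looks like a CV; identity mode expects an absolute SD (age %s)",
                              format(nd$S[i]), format(nd$M[i]),
                              format(nd$age_years[i])),
                      severity = "warning")
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(curve = character(), node = character(),
                      rule = character(), message = character(),
                      severity = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interpolate LMS coefficients at an arbitrary age
#'
#' Returns the tabulated (L, M, S) exactly when `age` coincides with a grid
#' node; otherwise linearly interpolates each of L, M and S between the two
#' bracketing nodes. Ages outside the curve's closed age domain raise an
#' out-of-domain error (no extrapolation, no clamping).
#'
#' @param curve A `reference_curve`.
#' @param age Query age in decimal years.
#' @return An `lms_node` carrying the query age and interpolated
#'   coefficients.
#' @export
#' @examples
#' cv <- reference_curve("height", "male",
#'   data.frame(age_years = c(2, 3), L = 1, M = c(80, 86), S = c(3, 3.4)))
#' interpolate_lms(cv, 2.5)
interpolate_lms <- function(curve, age) {
  ages <- curve$nodes$age_years
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age)) {
    agrowth_error("age must be a finite numeric scalar",
                  "agrowth_domain_error")
  }
  if (age < ages[1L] || age > ages[length(ages)]) {
    agrowth_error(sprintf(
      "age %s outside reference domain [%s, %s] for (%s, %s)",
      format(age), format(ages[1L]), format(ages[length(ages)]),
      curve$parameter, curve$sex),
      "agrowth_domain_error",
      age = age, age_min = ages[1L], age_max = ages[length(ages)])
  }
  hit <- match(age, ages)
  if (!is.na(hit)) {
    nd <- curve$nodes[hit, ]
    return(lms_node(age, nd$L, nd$M, nd$S))
  }
  i <- findInterval(age, ages)
  a0 <- ages[i]; a1 <- ages[i + 1L]
  w <- (age - a0) / (a1 - a0)
  lerp <- function(col) {
    v0 <- curve$nodes[[col]][i]
    v0 + w * (curve$nodes[[col]][i + 1L] - v0)
  }
  lms_node(age, lerp("L"), lerp("M"), lerp("S"))
}
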