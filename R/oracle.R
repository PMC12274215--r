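# Step-by-step manual LMS oracle.
#
# This mirrors what a clinician does with printed chart tables: look up the
# two bracketing rows by eye, interpolate L, M and S by hand, and plug into
# the printed formula. It deliberately shares no code with the engine — no
# interpolate_lms(), no zscore_*(), no registry dispatch — so that agreement
# between the two paths is evidence of correctness, not a tautology.

# Parameters whose charts require the full Box-Cox transform; all others
# tabulate L = 1 and use the plain (X - M)/S standardisation.
.oracle_boxcox_parameters <- c("weight", "bmi")

#' Manual step-by-step LMS z-score (independent oracle)
#'
#' Recomputes a z-score from a flat table of reference nodes using an
#' explicit bracketing-row search, hand-rolled linear interpolation of each
#' coefficient, and direct evaluation of the printed LMS formulas. Used as
#' the implementation-independent gold standard in [agreement_check()].
#'
#' @param nodes Flat reference table (data frame with columns
#'   `parameter,sex,age_years,L,M,S`, e.g. `as.data.frame(ref)`).
#' @param parameter,sex,age,value The observation to score.
#' @return The z-score as a plain number.
#' @export
manual_zscore <- function(nodes, parameter, sex, age, value) {
  rows <- nodes[nodes$parameter == parameter & nodes$sex == sex, , drop = FALSE]
  if (!nrow(rows)) stop("oracle: no rows for ", parameter, "/", sex)
  rows <- rows[order(rows$age_years), , drop = FALSE]
  if (age < rows$age_years[1] || age > rows$age_years[nrow(rows)]) {
    stop("oracle: age ", age, " outside table range")
  }
  # bracketing-row search, one row at a time
  lo <- NA_integer_
  for (i in seq_len(nrow(rows))) {
    if (rows$age_years[i] <= age) lo <- i else break
  }
  if (rows$age_years[lo] == age) {
    L <- rows$L[lo]; M <- rows$M[lo]; S <- rows$S[lo]
  } else {
    hi <- lo + 1L
    a0 <- rows$age_years[lo]; a1 <- rows$age_years[hi]
    frac <- (age - a0) / (a1 - a0)
    L <- rows$L[lo] + frac * (rows$L[hi] - rows$L[lo])
    M <- rows$M[lo] + frac * (rows$M[hi] - rows$M[lo])
    S <- rows$S[lo] + frac * (rows$S[hi] - rows$S[lo])
  }
  if (parameter %in% .oracle_boxcox_parameters) {
    if (abs(L) < 1e-7) {
      log(value / M) / S
    } else {
      ((value / M)^L - 1) / (L * S)
    }
  } else {
    (value - M) / S
  }
}
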