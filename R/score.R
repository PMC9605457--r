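# Pulse-variability score from paired pre/post profiles, and the one- and
# two-threshold decision rules.

PV_DEFAULT_FEATURES <- c("CV2", "P1_SD", "P2_SD", "P3_SD", "P4_SD", "P5_SD")

# pull a named index ("C3", "CV2", "P4_SD", "P7") out of a harmonic_profile
#' @keywords internal
profile_index <- function(profile, name) {
  m <- regmatches(name, regexec("^(C|CV|P)([0-9]+)(_SD)?$", name))[[1]]
  if (length(m) == 0L) {
    abort_pv("pulsevar_invalid_parameter", "unknown index name '%s'", name)
  }
  fam <- if (m[4] == "_SD") "P_SD" else m[2]
  n <- as.integer(m[3])
  if (n < 1L || n > 10L) {
    abort_pv("pulsevar_invalid_parameter", "harmonic number out of range in '%s'", name)
  }
  unname(profile[[fam]][n])
}

#' Paired pre/post features for one subject
#'
#' @param subject_id subject identifier.
#' @param pre,post `harmonic_profile`s of the M0 (pre) and M1 (post)
#'   sessions, same channel.
#' @param label group label: `"N"`, `"C"` or `"V"`; `cv_flag` is derived as
#'   label in \{C, V\}.
#' @return An object of class `paired_features`.
#' @export
paired_features <- function(subject_id, pre, post, label = c("N", "C", "V")) {
  label <- match.arg(label)
  structure(
    list(subject_id = subject_id, pre = pre, post = post,
         label = label, cv_flag = label %in% c("C", "V")),
    class = "paired_features"
  )
}

#' Pulse-variability score
#'
#' The product of the post/pre ratios of the selected variability indices,
#' by default CV2 and P1_SD..P5_SD:
#' \deqn{score = \frac{CV_2^{M1} \cdot P_{1,SD}^{M1} \cdots P_{5,SD}^{M1}}
#'                    {CV_2^{M0} \cdot P_{1,SD}^{M0} \cdots P_{5,SD}^{M0}}}
#' Equal sessions give 1; doubling every selected index at M1 gives
#' \eqn{2^6 = 64}; swapping the sessions inverts the score. Each index is the
#' per-recording aggregate over beats (no further averaging).
#'
#' @param pre,post `harmonic_profile`s (M0 and M1), or pass a
#'   `paired_features` object as `pre`.
#' @param features character vector of index names entering the product.
#' @param eps guard: any denominator index below `eps` raises a
#'   degenerate-score error naming the offending index (zero-dispersion
#'   recordings would otherwise divide by zero).
#' @return The score, a positive dimensionless scalar.
#' @export
pv_score <- function(pre, post = NULL, features = PV_DEFAULT_FEATURES,
                     eps = 1e-9) {
  if (inherits(pre, "paired_features")) {
    post <- pre$post
    pre <- pre$pre
  }
  num <- vapply(features, profile_index, numeric(1), profile = post)
  den <- vapply(features, profile_index, numeric(1), profile = pre)
  bad <- !is.finite(den) | den <= eps
  if (any(bad)) {
    abort_pv("pulsevar_degenerate_score",
             "degenerate denominator index: %s",
             paste(features[bad], collapse = ", "))
  }
  if (any(!is.finite(num) | num < 0)) {
    abort_pv("pulsevar_degenerate_score", "non-finite numerator index")
  }
  prod(num / den)
}

#' Single-threshold decision
#'
#' Positive iff score is strictly above the threshold (the boundary itself is
#' negative; exact-boundary values are vanishingly likely on a continuous
#' score).
#'
#' @param score numeric vector of scores.
#' @param threshold positive cutoff.
#' @return Character vector in \{"positive", "negative"\}.
#' @export
classify_single <- function(score, threshold) {
  if (!is.finite(threshold) || threshold <= 0) {
    abort_pv("pulsevar_invalid_parameter", "threshold must be > 0")
  }
  ifelse(score > threshold, "positive", "negative")
}

#' Two-threshold decision with an ambiguity band
#'
#' Positive strictly above `high`, negative strictly below `low`; scores in
#' `[low, high]` (endpoints included) are excluded as ambiguous and receive
#' no classification.
#'
#' @param score numeric vector of scores.
#' @param low,high band limits, `0 < low < high`.
#' @return Character vector in \{"positive", "negative", "excluded"\}.
#' @export
classify_band <- function(score, low, high) {
  if (!is.finite(low) || !is.finite(high) || low <= 0 || low >= high) {
    abort_pv("pulsevar_invalid_band", "need 0 < low < high (got %g, %g)", low, high)
  }
  ifelse(score > high, "positive", ifelse(score < low, "negative", "excluded"))
}

#' Score every subject of a profiled cohort
#'
#' Computes the pulse-variability score from the M0 and M1 rows of a feature
#' table (as produced by [profiles_table()]).
#'
#' @param profiles data.frame with columns subject, session and the 40 index
#'   columns.
#' @param features,eps passed to the score (see [pv_score()]).
#' @return data.frame: subject, score.
#' @export
score_table <- function(profiles, features = PV_DEFAULT_FEATURES, eps = 1e-9) {
  subjects <- unique(profiles$subject)
  score <- vapply(subjects, function(s) {
    m0 <- profiles[profiles$subject == s & profiles$session == "M0", , drop = FALSE]
    m1 <- profiles[profiles$subject == s & profiles$session == "M1", , drop = FALSE]
    if (nrow(m0) != 1L || nrow(m1) != 1L) {
      abort_pv("pulsevar_missing_data", "subject %s lacks an M0 or M1 row", s)
    }
    num <- as.numeric(m1[1, features])
    den <- as.numeric(m0[1, features])
    bad <- !is.finite(den) | den <= eps
    if (any(bad)) {
      abort_pv("pulsevar_degenerate_score", "degenerate denominator index: %s (subject %s)",
               paste(features[bad], collapse = ", "), s)
    }
    prod(num / den)
  }, numeric(1))
  data.frame(subject = subjects, score = unname(score), stringsAsFactors = FALSE)
}
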