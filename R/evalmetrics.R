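# Confusion counts and the derived operating-point metrics: accuracy,
# specificity, sensitivity, single-operating-point AUC, positive likelihood
# ratio, rank AUC and adopted/excluded proportions.

# coerce labels to 0/1 integers
#' @keywords internal
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c("0", "1"))) {
      abort_pv("pulsevar_invalid_parameter",
               "character labels must be '0'/'1', got: %s", paste(u, collapse = ", "))
    }
    return(as.integer(labels))
  }
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) {
    abort_pv("pulsevar_invalid_parameter", "labels must be binary (0/1)")
  }
  labels
}

#' Confusion matrix and derived metrics
#'
#' Tallies decisions against binary labels. Excluded decisions (from the
#' ambiguity band) are dropped from the counts but tallied, and accuracy,
#' specificity and sensitivity are computed over the adopted subjects only.
#' The reported AUC is the single-operating-point value
#' (sensitivity + specificity)/2, see [binary_auc()].
#'
#' @param decisions character vector in \{"positive", "negative", "excluded"\}.
#' @param labels binary labels (1 = condition present), same length.
#' @return A `classification_report`: counts `tp`, `fp`, `tn`, `fn`,
#'   `n_excluded`, `n`; `accuracy` (percent of adopted), `specificity`,
#'   `sensitivity`, `auc` (fractions), `lr_plus`, `adopted_proportion`
#'   (percent).
#' @export
confusion <- function(decisions, labels) {
  labels <- as_binary_labels(labels)
  if (length(decisions) != length(labels)) {
    abort_pv("pulsevar_invalid_parameter", "decisions and labels differ in length")
  }
  if (any(!decisions %in% c("positive", "negative", "excluded"))) {
    abort_pv("pulsevar_invalid_parameter",
             "decisions must be 'positive', 'negative' or 'excluded'")
  }
  adopted <- decisions != "excluded"
  if (!any(adopted)) {
    abort_pv("pulsevar_empty_report", "no adopted subjects: every decision is excluded")
  }
  pos <- decisions == "positive"
  tp <- sum(pos & labels == 1L)
  fp <- sum(pos & labels == 0L)
  tn <- sum(!pos & adopted & labels == 0L)
  fn <- sum(!pos & adopted & labels == 1L)
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         n_excluded = sum(!adopted), n = length(decisions),
         accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
         specificity = specificity, sensitivity = sensitivity,
         auc = binary_auc(sensitivity, specificity),
         lr_plus = if (is.na(specificity) || is.na(sensitivity)) NA_real_
                   else likelihood_ratio_positive(sensitivity, specificity),
         adopted_proportion = 100 * sum(adopted) / length(decisions)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report>\n")
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(truth = c("0", "1"), decision = c("negative", "positive")))
  print(m)
  cat(sprintf("excluded: %d of %d (adopted %.1f%%)\n",
              x$n_excluded, x$n, x$adopted_proportion))
  cat(sprintf("accuracy %.2f%%  specificity %.2f  sensitivity %.2f  AUC %.2f  LR+ %.2f\n",
              x$accuracy, x$specificity, x$sensitivity, x$auc, x$lr_plus))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report a `classification_report`.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Single-operating-point AUC
#'
#' The area under the ROC curve formed by one operating point
#' (1 - specificity, sensitivity) joined to (0,0) and (1,1):
#' (sensitivity + specificity) / 2. This is the AUC arithmetic behind
#' threshold classifiers reported at a single cutoff.
#'
#' @param sensitivity,specificity fractions in [0, 1].
#' @return AUC fraction.
#' @export
binary_auc <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Rank (Mann-Whitney) AUC for continuous scores
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half; computed from mid-ranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels.
#' @return AUC fraction.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort_pv("pulsevar_undefined_auc", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Positive likelihood ratio
#'
#' sensitivity / (1 - specificity): how many times more likely a positive
#' test result is in subjects with the condition than without it. A
#' specificity of 1 yields `Inf` (reported, not an error).
#'
#' @param sensitivity,specificity fractions in [0, 1].
#' @return LR+ (positive real or `Inf`).
#' @export
likelihood_ratio_positive <- function(sensitivity, specificity) {
  if (specificity >= 1) return(Inf)
  sensitivity / (1 - specificity)
}

#' Proportion of subjects adopted (outside the ambiguity band)
#'
#' @param report a `classification_report`.
#' @return Percent of the cohort that received a classification.
#' @export
adopted_proportion <- function(report) {
  if (report$n <= 0) {
    abort_pv("pulsevar_invalid_parameter", "empty cohort")
  }
  100 * (report$tp + report$fp + report$tn + report$fn) / report$n
}
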