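# Multi-classifier baseline: the eight named supervised models trained on
# the 40-index feature table with stratified threefold cross-validation.

FEATURE40 <- c(paste0("C", 1:10), paste0("CV", 1:10),
               paste0("P", 1:10), paste0("P", 1:10, "_SD"))

#' Assemble a feature table from recording profiles
#'
#' Two modes:
#' * `pulse40`: one row per subject, the 40 indices of the requested session
#'   (which session the original analysis used is not documented; M1 is the
#'   default).
#' * `delta40`: one row per subject, M1-vs-M0 change features: log-ratios
#'   log(M1/M0) for the positive families C, CV and P_SD, and wrapped phase
#'   differences (degrees) for P, whose sign-indefinite circular values do
#'   not admit a log-ratio.
#'
#' @param profiles data.frame from [profiles_table()].
#' @param labels data.frame with columns subject, group (as from
#'   [simulate_cohort()]).
#' @param mode `"pulse40"` or `"delta40"`.
#' @param session session used in `pulse40` mode.
#' @param target `"cv_flag"` (groups C and V positive) or `"v_flag"`
#'   (group V positive).
#' @return A `feature_table`: matrix `x` (subjects x 40), integer `y`,
#'   `subjects`, `feature_names`.
#' @export
assemble_features <- function(profiles, labels, mode = c("pulse40", "delta40"),
                              session = "M1", target = c("cv_flag", "v_flag")) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  subjects <- labels$subject
  get_row <- function(s, sess) {
    r <- profiles[profiles$subject == s & profiles$session == sess, FEATURE40,
                  drop = FALSE]
    if (nrow(r) != 1L) return(NULL)
    as.numeric(r[1, ])
  }
  if (mode == "pulse40") {
    rows <- lapply(subjects, get_row, sess = session)
    missing <- subjects[vapply(rows, is.null, logical(1))]
    if (length(missing) > 0L) {
      abort_pv("pulsevar_missing_data", "subjects lacking session %s: %s",
               session, paste(missing, collapse = ", "))
    }
    x <- do.call(rbind, rows)
  } else {
    m0 <- lapply(subjects, get_row, sess = "M0")
    m1 <- lapply(subjects, get_row, sess = "M1")
    missing <- subjects[vapply(m0, is.null, logical(1)) |
                          vapply(m1, is.null, logical(1))]
    if (length(missing) > 0L) {
      abort_pv("pulsevar_missing_data", "subjects lacking M0 or M1: %s",
               paste(missing, collapse = ", "))
    }
    is_phase <- grepl("^P[0-9]+$", FEATURE40)
    x <- t(mapply(function(a, b) {
      out <- numeric(length(a))
      out[!is_phase] <- log(b[!is_phase] / a[!is_phase])
      out[is_phase] <- wrap_deg(b[is_phase] - a[is_phase])
      out
    }, m0, m1))
  }
  if (any(!is.finite(x))) {
    abort_pv("pulsevar_missing_data", "non-finite feature values after assembly")
  }
  colnames(x) <- FEATURE40
  y <- if (target == "cv_flag") as.integer(labels$group %in% c("C", "V"))
       else as.integer(labels$group == "V")
  structure(list(x = x, y = y, subjects = subjects, feature_names = FEATURE40,
                 target = target),
            class = "feature_table")
}

# deterministic stratified fold assignment: depends only on (seed, y)
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k) {
    abort_pv("pulsevar_stratification",
             "smallest class has fewer members (%d) than folds (%d)",
             min(table(y)), k)
  }
  folds <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated baseline over the eight classifier families
#'
#' Trains SVM, MLP, GNB, DT, RF, LR, LDA and KNN on stratified k-fold splits
#' (default threefold, matching the small-cohort setting where unstratified
#' folds risk single-class test sets). Features are z-scored with the
#' training-fold statistics before every fit. Metrics are computed per fold
#' through the same [confusion()] / [rank_auc()] code path as the score
#' analysis and averaged over folds. Deterministic given `seed`.
#'
#' @param ft a `feature_table` from [assemble_features()].
#' @param seed integer seed controlling folds and stochastic fits.
#' @param folds number of folds.
#' @param models subset of `c("svm","mlp","gnb","dt","rf","lr","lda","knn")`.
#' @return data.frame: model, accuracy (percent), auc, specificity,
#'   sensitivity (fold means).
#' @export
crossval_models <- function(ft, seed = 1, folds = 3L,
                            models = names(PV_MODELS)) {
  models <- match.arg(models, names(PV_MODELS), several.ok = TRUE)
  fold_id <- stratified_folds(ft$y, folds, seed)
  out <- lapply(models, function(m) {
    met <- matrix(NA_real_, folds, 4,
                  dimnames = list(NULL, c("accuracy", "auc", "specificity", "sensitivity")))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      mu <- colMeans(ft$x[tr, , drop = FALSE])
      sdv <- apply(ft$x[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(ft$x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(ft$x[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      fit <- with_local_seed(seed + f, PV_MODELS[[m]](xtr, ft$y[tr]))
      sc <- predict_score(fit, xte)
      dec <- ifelse(sc > score_cut(fit), "positive", "negative")
      rep <- confusion(dec, ft$y[!tr])
      met[f, ] <- c(rep$accuracy, rank_auc(sc, ft$y[!tr]),
                    rep$specificity, rep$sensitivity)
    }
    data.frame(model = m, t(colMeans(met)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
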