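# Per-beat Fourier harmonic decomposition and the 40 aggregate indices
# Cn, CVn, Pn, Pn_SD (n = 1..10), plus HR and HR_CV.

IDX_FAMILIES <- c("C", "CV", "P", "P_SD")

#' Harmonic amplitudes and phases of one beat
#'
#' Computes the Fourier coefficients of a beat at exact multiples of the
#' beat's own fundamental (period = segment length), i.e.
#' \eqn{a_n = (2/N) \sum_t s_t e^{-i 2\pi n t / N}} for n = 1..10, with
#' \eqn{a_0} the mean. No zero-padding or fixed-grid FFT: each beat is
#' analysed on its own period so harmonic numbers stay aligned across beats
#' of different lengths. Phases follow the cosine convention
#' (\eqn{s = |a_n| \cos(2\pi n t/T + \phi_n)}), referenced to the beat foot;
#' a sub-sample foot offset `frac` (in samples, from the detector) rotates
#' phase n by \eqn{360 n \cdot frac / N} degrees so the reference is the true
#' foot instant rather than the sample grid.
#'
#' @param beat numeric vector, one beat's samples (foot to next foot).
#' @param fs sampling rate, Hz.
#' @param frac sub-sample offset of the true foot within the first sample
#'   (0 <= frac < 1).
#' @return A `beat_harmonics` object: `amplitudes` (n = 0..10, signal units),
#'   `phases_deg` (n = 1..10, wrapped to (-180, 180]), `period_s`.
#' @export
beat_harmonics <- function(beat, fs, frac = 0) {
  n_samp <- length(beat)
  if (n_samp < 40L) {
    abort_pv("pulsevar_invalid_beat",
             "beat has %d samples; at least 40 required", n_samp)
  }
  F <- stats::fft(beat)
  an <- 2 * F[2:11] / n_samp
  structure(
    list(amplitudes = c(Re(F[1]) / n_samp, Mod(an)),
         phases_deg = wrap_deg(Arg(an) * 180 / pi + 360 * (1:10) * frac / n_samp),
         period_s = n_samp / fs),
    class = "beat_harmonics"
  )
}

#' Amplitude proportions of one beat
#'
#' \eqn{C_n = 100 |a_n| / \sum_{k=1}^{10} |a_k|} (the `"sum"` dialect,
#' default): a literal proportion, scale-free, summing to 100 exactly. The
#' `"fundamental"` dialect divides by \eqn{|a_1|} instead (then \eqn{C_1} is
#' 100 and the values do not sum to 100); it is provided because the
#' normalization used in the field is not unique.
#'
#' @param bh a `beat_harmonics` object.
#' @param norm `"sum"` or `"fundamental"`.
#' @return Numeric vector of 10 proportions (percent).
#' @export
amplitude_proportions <- function(bh, norm = c("sum", "fundamental")) {
  norm <- match.arg(norm)
  a <- bh$amplitudes[2:11]
  denom <- if (norm == "sum") sum(a) else a[1]
  # relative floor: a constant beat leaves only numerical dust in bins 1..10
  if (denom <= 1e-9 * max(abs(bh$amplitudes[1]), .Machine$double.xmin)) {
    abort_pv("pulsevar_invalid_beat", "all harmonic amplitudes are zero")
  }
  100 * a / denom
}

# circular mean (deg) and circular SD (deg, from the resultant length R:
# sd = sqrt(-2 log R)); reduces to the linear SD as dispersion -> 0
#' @keywords internal
circular_stats <- function(theta_deg) {
  z <- mean(exp(1i * theta_deg * pi / 180))
  R <- min(Mod(z), 1)
  c(mean = wrap_deg(Arg(z) * 180 / pi),
    sd = if (R <= .Machine$double.eps) Inf else sqrt(-2 * log(R)) * 180 / pi)
}

#' Aggregate per-beat harmonics into the 40 recording-level indices
#'
#' For each harmonic n = 1..10 over the beats of one recording:
#' * `C`: mean of the per-beat amplitude proportions (percent);
#' * `CV`: coefficient of variation of the per-beat proportions (percent,
#'   sample SD; defined as 0 when the mean proportion is 0);
#' * `P`: mean phase (degrees; circular by default);
#' * `P_SD`: dispersion of the per-beat phases (degrees; circular SD from the
#'   resultant length by default, which is wrap-safe at +-180 and equals the
#'   linear SD in the small-dispersion limit).
#'
#' HR and HR_CV are computed from the beat periods.
#'
#' @param bh_list list of `beat_harmonics` (>= 3 beats).
#' @param phase_sd `"circular"` (default) or `"linear"` (plain SD of the
#'   wrapped phases; fallback dialect).
#' @param cn_norm passed to [amplitude_proportions()].
#' @return A `harmonic_profile`: numeric vectors `C`, `CV`, `P`, `P_SD`
#'   (length 10, named H1..H10), scalars `HR`, `HR_CV`, `n_beats`.
#' @export
aggregate_profile <- function(bh_list, phase_sd = c("circular", "linear"),
                              cn_norm = "sum") {
  phase_sd <- match.arg(phase_sd)
  if (length(bh_list) < 3L) {
    abort_pv("pulsevar_insufficient_beats",
             "need at least 3 beats, got %d", length(bh_list))
  }
  Cmat <- t(vapply(bh_list, amplitude_proportions, numeric(10), norm = cn_norm))
  Pmat <- t(vapply(bh_list, function(b) b$phases_deg, numeric(10)))
  periods <- vapply(bh_list, function(b) b$period_s, numeric(1))

  C <- colMeans(Cmat)
  CV <- vapply(seq_len(10), function(n) {
    if (C[n] == 0) 0 else 100 * stats::sd(Cmat[, n]) / C[n]
  }, numeric(1))
  if (phase_sd == "circular") {
    cs <- apply(Pmat, 2, circular_stats)
    P <- cs["mean", ]
    P_SD <- cs["sd", ]
  } else {
    P <- wrap_deg(colMeans(Pmat))
    P_SD <- apply(Pmat, 2, stats::sd)
  }
  hr <- heart_rate_stats(periods)
  nm <- paste0("H", 1:10)
  structure(
    list(C = stats::setNames(C, nm), CV = stats::setNames(CV, nm),
         P = stats::setNames(unname(P), nm), P_SD = stats::setNames(unname(P_SD), nm),
         HR = unname(hr["HR"]), HR_CV = unname(hr["HR_CV"]),
         n_beats = length(bh_list)),
    class = "harmonic_profile"
  )
}

#' Full profile of one recording
#'
#' Segments the recording (unless a `beat_set` is supplied, e.g. the
#' simulator's ground truth from [true_beatset()]), decomposes every beat and
#' aggregates the 40 indices. HR/HR_CV come from the detected foot-to-foot
#' intervals when available, otherwise from the beat periods.
#'
#' @param rec a `pulse_recording`.
#' @param beats optional `beat_set`; default runs [detect_feet()].
#' @param ... passed to [aggregate_profile()] (`phase_sd`, `cn_norm`).
#' @return A `harmonic_profile`.
#' @export
harmonic_profile <- function(rec, beats = NULL, ...) {
  if (is.null(beats)) beats <- detect_feet(rec)
  bh <- Map(beat_harmonics, beats$beats, frac = beats$frac, fs = rec$fs)
  prof <- aggregate_profile(bh, ...)
  hr <- heart_rate_stats(beats)
  prof$HR <- unname(hr["HR"])
  prof$HR_CV <- unname(hr["HR_CV"])
  prof
}

#' @export
print.harmonic_profile <- function(x, ...) {
  cat(sprintf("<harmonic_profile> %d beats, HR %.1f bpm, HR_CV %.2f%%\n",
              x$n_beats, x$HR, x$HR_CV))
  m <- rbind(C = x$C, CV = x$CV, P = x$P, P_SD = x$P_SD)
  print(round(m, 2))
  invisible(x)
}

#' Flatten a profile to one feature-table row
#'
#' @param profile a `harmonic_profile`.
#' @param subject,session,channel identifiers for the row.
#' @return A 1-row data.frame: subject, session, channel, HR, HR_CV,
#'   C1..C10, CV1..CV10, P1..P10, P1_SD..P10_SD.
#' @export
profile_row <- function(profile, subject = "S1", session = "M0",
                        channel = "BPW") {
  vals <- c(profile$C, profile$CV, profile$P, profile$P_SD)
  names(vals) <- c(paste0("C", 1:10), paste0("CV", 1:10),
                   paste0("P", 1:10), paste0("P", 1:10, "_SD"))
  cbind(
    data.frame(subject = subject, session = session, channel = channel,
               HR = profile$HR, HR_CV = profile$HR_CV,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(vals))
  )
}

#' Profile every recording of a cohort
#'
#' @param cohort a `pulse_cohort` from [simulate_cohort()], or a named list
#'   of `pulse_recording`s.
#' @param segmentation `"detect"` (run [detect_feet()]) or `"truth"` (use the
#'   simulator's exact beat boundaries).
#' @param ... passed to [harmonic_profile()].
#' @return A data.frame with one [profile_row()] per recording.
#' @export
profiles_table <- function(cohort, segmentation = c("detect", "truth"), ...) {
  segmentation <- match.arg(segmentation)
  recs <- if (inherits(cohort, "pulse_cohort")) cohort$recordings else cohort
  rows <- lapply(recs, function(rec) {
    bs <- if (segmentation == "truth") true_beatset(rec) else NULL
    profile_row(harmonic_profile(rec, beats = bs, ...),
                subject = rec$subject_id, session = rec$session,
                channel = rec$channel)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
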