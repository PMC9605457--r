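# Beat-onset ("foot") detection and heart-rate statistics.
#
# Detection runs on a band-pass conditioned copy of the signal; harmonic
# extraction always uses the raw samples so conditioning cannot bias Cn.

# zero-phase brick-wall band-pass via FFT bin masking
#' @keywords internal
bandpass_fft <- function(x, fs, low = 0.5, high = 40) {
  n <- length(x)
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  keep <- f >= low & f <= high
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

# local maxima above `height`, at least `min_dist` samples apart (greedy by size)
#' @keywords internal
find_peaks <- function(x, height, min_dist) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                 x[2:(n - 1)] >= height) + 1L
  if (length(idx) == 0L) return(integer(0))
  idx <- idx[order(x[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (all(abs(i - kept) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# internal beat_set constructor: segments a recording at fractional foot
# positions (0-based sample units). Segment b spans samples
# floor(pos[b])+1 .. floor(pos[b+1]) (1-based); the sub-sample remainder is
# kept as a per-beat fractional offset used to reference harmonic phases to
# the true foot instant rather than the sample grid.
#' @keywords internal
new_beat_set <- function(foot_pos, rec, reject_outliers = TRUE) {
  foot_pos <- sort(foot_pos)
  fs <- rec$fs
  intervals <- diff(foot_pos) / fs
  valid <- rep(TRUE, length(intervals))
  if (reject_outliers && length(intervals) > 0L) {
    valid <- intervals >= 0.33 & intervals <= 1.5
    if (any(valid)) {
      med <- stats::median(intervals[valid])
      valid <- valid & abs(intervals - med) <= 0.3 * med
    }
  }
  if (sum(valid) < 3L) {
    abort_pv("pulsevar_insufficient_beats",
             "fewer than 3 valid beats detected (%d)", sum(valid))
  }
  k0 <- floor(foot_pos)
  beats <- vector("list", sum(valid))
  frac <- numeric(sum(valid))
  j <- 0L
  for (b in which(valid)) {
    j <- j + 1L
    beats[[j]] <- rec$samples[(k0[b] + 1L):k0[b + 1L]]
    frac[j] <- foot_pos[b] - k0[b]
  }
  structure(
    list(foot_pos = foot_pos,
         foot_indices = as.integer(round(foot_pos)),
         intervals_s = intervals[valid],
         beats = beats,
         frac = frac,
         fs = fs,
         n_rejected = sum(!valid)),
    class = "beat_set"
  )
}

#' Detect beat onsets in a pulse recording
#'
#' Locates one foot per cardiac cycle. Candidate beats are the maxima of the
#' signal upslope (first difference of a 0.5-40 Hz zero-phase conditioned
#' copy) separated by at least 0.33 s. For each upstroke the foot is placed
#' by the intersecting-tangent construction: the horizontal line through the
#' local minimum preceding the upstroke intersected with the tangent at the
#' point of maximum upslope. The intersection is a continuous (sub-sample)
#' time; beats are segmented at its integer part and the fractional remainder
#' is carried along so harmonic phases can be referenced to the true foot.
#'
#' Intervals outside 0.33-1.5 s (40-180 bpm) or deviating more than 30 percent from
#' the median interval are rejected as artifacts.
#'
#' @param rec a [pulse_recording()].
#' @param method `"tangent"` (intersecting tangents, default) or `"minimum"`
#'   (foot at the pre-upstroke minimum).
#' @param bandpass condition the detection copy with a 0.5-40 Hz zero-phase
#'   band-pass (recommended; segmentation always cuts the raw samples).
#' @return A `beat_set`: foot positions/indices, valid foot-to-foot intervals
#'   (s) and the per-beat raw sample segments.
#' @export
detect_feet <- function(rec, method = c("tangent", "minimum"), bandpass = TRUE) {
  method <- match.arg(method)
  fs <- rec$fs
  if (stats::sd(rec$samples) == 0) {
    abort_pv("pulsevar_insufficient_beats", "no upstrokes found (flat signal)")
  }
  x <- if (bandpass) bandpass_fft(rec$samples, fs) else rec$samples - mean(rec$samples)

  slope <- c(diff(x), 0) * fs
  w <- max(1L, round(fs * 0.01))
  if (w > 1L) slope <- stats::filter(slope, rep(1 / w, w), sides = 2)
  slope[is.na(slope)] <- 0
  slope <- as.numeric(slope)

  pos <- slope[slope > 0]
  if (length(pos) == 0L) {
    abort_pv("pulsevar_insufficient_beats", "no upstrokes found (flat signal?)")
  }
  thr <- 0.5 * stats::quantile(pos, 0.98, names = FALSE)
  if (thr <= 0) {
    abort_pv("pulsevar_insufficient_beats", "no upstrokes found (flat signal?)")
  }
  up <- find_peaks(slope, height = thr, min_dist = round(0.33 * fs))
  if (length(up) < 4L) {
    abort_pv("pulsevar_insufficient_beats",
             "only %d upstrokes detected", length(up))
  }

  # parabolic sub-sample refinement around a local extremum at index i
  refine <- function(v, i) {
    if (i <= 1L || i >= length(v)) return(c(pos = as.numeric(i), val = v[i]))
    d <- (v[i - 1L] - v[i + 1L]) / (2 * (v[i - 1L] - 2 * v[i] + v[i + 1L]))
    if (!is.finite(d) || abs(d) > 1) d <- 0
    c(pos = i + d, val = v[i] - 0.25 * (v[i - 1L] - v[i + 1L]) * d)
  }

  win <- round(0.35 * fs)
  foot_pos <- vapply(up, function(m) {
    lo <- max(1L, m - win)
    i_min <- lo - 1L + which.min(x[lo:m])
    fmin <- refine(x, i_min)
    if (method == "minimum" || slope[m] <= 0) return(fmin["pos"] - 1)
    # tangent at the (sub-sample) max upslope: y = x(m*) + s(m*) (k - m*)/fs;
    # foot where it meets the horizontal through the local minimum
    fsl <- refine(slope, m)
    m_star <- fsl["pos"]
    x_star <- x[m] + (m_star - m) * slope[m] / fs
    k_star <- m_star - (x_star - fmin["val"]) / (fsl["val"] / fs)
    unname(max(fmin["pos"], k_star) - 1)  # 0-based, not before the minimum
  }, numeric(1))

  foot_pos <- pmax(foot_pos, 0)
  foot_pos <- foot_pos[c(TRUE, diff(foot_pos) > 0.25 * fs)]
  new_beat_set(foot_pos, rec)
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d feet, %d valid beats (%d rejected), mean interval %.3f s\n",
              length(x$foot_pos), length(x$beats), x$n_rejected,
              mean(x$intervals_s)))
  invisible(x)
}

#' Heart rate and its coefficient of variation
#'
#' HR is 60 over the mean foot-to-foot interval; HR_CV is the coefficient of
#' variation of the intervals in percent, using the sample (n - 1) standard
#' deviation since recordings hold only ~60-90 beats.
#'
#' @param bs a `beat_set`, or a numeric vector of intervals in seconds.
#' @return Named numeric vector `c(HR = beats/min, HR_CV = %)`.
#' @export
heart_rate_stats <- function(bs) {
  intervals <- if (inherits(bs, "beat_set")) bs$intervals_s else as.numeric(bs)
  if (length(intervals) < 3L) {
    abort_pv("pulsevar_insufficient_beats",
             "need at least 3 intervals, got %d", length(intervals))
  }
  m <- mean(intervals)
  c(HR = 60 / m, HR_CV = 100 * stats::sd(intervals) / m)
}
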