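#' Beat template: harmonic content of one canonical pulse beat
#'
#' A beat is modelled as a truncated Fourier series
#' \eqn{s(t) = b + \sum_{n=1}^{10} A_n \cos(2\pi n t/T + \phi_n)} over one
#' period \eqn{T}. The template holds the ten harmonic amplitudes \eqn{A_n}
#' (arbitrary pressure units), the ten phase angles \eqn{\phi_n} (degrees,
#' wrapped to (-180, 180]) and a DC baseline. Extracted amplitude proportions
#' and phases of a rendered beat recover these values exactly, which makes the
#' template the ground truth for round-trip validation.
#'
#' @param amplitudes numeric(10), non-negative harmonic amplitudes; the
#'   fundamental must be nonzero.
#' @param phases_deg numeric(10), phases in degrees (wrapped on input).
#' @param baseline DC level added to the waveform.
#' @return An object of class `beat_template`.
#' @seealso [default_beat_template()], [render_beat()]
#' @export
beat_template <- function(amplitudes, phases_deg, baseline = 0) {
  if (length(amplitudes) != 10L || length(phases_deg) != 10L) {
    abort_pv("pulsevar_invalid_parameter",
             "a beat template needs exactly 10 amplitudes and 10 phases")
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    abort_pv("pulsevar_invalid_parameter", "harmonic amplitudes must be finite and >= 0")
  }
  if (amplitudes[1] == 0) {
    abort_pv("pulsevar_invalid_parameter", "the fundamental (harmonic 1) must be nonzero")
  }
  structure(
    list(amplitudes = as.numeric(amplitudes),
         phases_deg = wrap_deg(as.numeric(phases_deg)),
         baseline   = as.numeric(baseline)),
    class = "beat_template"
  )
}

#' Default radial-pulse beat template
#'
#' Amplitudes decay monotonically with harmonic number, as measured radial
#' pressure pulses do (the first three harmonics dominate, C1 around 46%;
#' proportions of harmonics 5-10 are an order of magnitude smaller). The
#' phases are those of a smooth single-upstroke systolic wave (a skewed
#' \eqn{u^2 (1-u)^6} pulse), which keeps the rendered beat unimodal with one
#' steep upstroke so that foot detection has an unambiguous target. The
#' template is foot-aligned: rotated so the waveform minimum sits at t = 0,
#' making concatenated beats join at their feet.
#'
#' @return A foot-aligned `beat_template`.
#' @export
default_beat_template <- function() {
  tpl <- beat_template(
    amplitudes = c(1, 0.48, 0.27, 0.16, 0.10, 0.065, 0.042, 0.028, 0.019, 0.013),
    phases_deg = c(-104.8, 176, 145.8, 131.4, 123, 117.5, 113.5, 110.6, 108.3, 106.4),
    baseline   = 2
  )
  align_template_foot(tpl)
}

#' Rotate a beat template so its minimum lies at the beat onset
#'
#' Shifts the time origin of the template waveform to its global minimum over
#' one period, adding \eqn{360 n u} degrees to harmonic \eqn{n} for a shift of
#' \eqn{u} periods. Beats rendered from an aligned template start at their own
#' foot, which gives foot detection an exact target.
#'
#' @param template a `beat_template`.
#' @param resolution grid points per period used to locate the minimum.
#' @return A foot-aligned `beat_template`.
#' @export
align_template_foot <- function(template, resolution = 4096L) {
  u <- seq(0, 1, length.out = resolution + 1L)[-(resolution + 1L)]
  ph <- template$phases_deg * pi / 180
  s <- template$baseline
  for (n in 1:10) s <- s + template$amplitudes[n] * cos(2 * pi * n * u + ph[n])
  u_min <- u[which.min(s)]
  beat_template(template$amplitudes,
                wrap_deg(template$phases_deg + 360 * (1:10) * u_min),
                template$baseline)
}

#' Beat-to-beat jitter model
#'
#' Describes the physiological variability the simulator superimposes on a
#' beat template: the beat-interval distribution (log-normal with given mean
#' and coefficient of variation, truncated to the physiological 0.33-1.5 s
#' range, i.e. 40-180 bpm), multiplicative per-beat amplitude jitter (drives
#' the extracted CVn), additive per-beat wrapped-normal phase jitter (drives
#' Pn_SD) and white measurement noise.
#'
#' @param rr_mean mean beat interval in seconds.
#' @param rr_cv coefficient of variation of the beat interval (fraction; the
#'   extracted HR_CV is 100 times this).
#' @param amp_jitter_cv per-harmonic multiplicative amplitude jitter
#'   (fraction; scalar or length 10).
#' @param phase_jitter_sd per-harmonic phase jitter SD in degrees (scalar or
#'   length 10).
#' @param noise_sd SD of additive white noise, in signal units.
#' @param seed optional integer; if set, [simulate_recording()] is
#'   bit-reproducible for identical configuration.
#' @return An object of class `jitter_model`.
#' @export
jitter_model <- function(rr_mean = 0.8, rr_cv = 0.04, amp_jitter_cv = 0.05,
                         phase_jitter_sd = 5, noise_sd = 0.01, seed = NULL) {
  if (!is.finite(rr_mean) || rr_mean <= 0) {
    abort_pv("pulsevar_invalid_parameter", "rr_mean must be > 0")
  }
  disp <- c(rr_cv, amp_jitter_cv, phase_jitter_sd, noise_sd)
  if (any(!is.finite(disp)) || any(disp < 0)) {
    abort_pv("pulsevar_invalid_parameter", "all dispersion parameters must be >= 0")
  }
  structure(
    list(rr_mean = rr_mean, rr_cv = rr_cv,
         amp_jitter_cv = rep_len(amp_jitter_cv, 10L),
         phase_jitter_sd = rep_len(phase_jitter_sd, 10L),
         noise_sd = noise_sd, seed = seed),
    class = "jitter_model"
  )
}

#' Render one beat from a template
#'
#' Samples \eqn{b + \sum_n A_n \cos(2\pi n t/T + \phi_n)} on \eqn{[0, T)} at
#' rate `fs`. The realized period is quantized to the sample grid
#' (`T = round(fs * rr) / fs`) so every beat is exactly periodic on its own
#' samples and harmonic extraction is leakage-free by construction.
#'
#' @param template a `beat_template`.
#' @param rr beat interval in seconds.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of `round(fs * rr)` samples.
#' @export
render_beat <- function(template, rr, fs) {
  if (!is.finite(rr) || rr <= 0 || !is.finite(fs) || fs <= 0) {
    abort_pv("pulsevar_invalid_parameter", "rr and fs must be positive")
  }
  n_samp <- round(fs * rr)
  if (n_samp < 40) {
    abort_pv("pulsevar_invalid_parameter",
             "fs * rr must give at least 40 samples per beat (got %d)", n_samp)
  }
  k <- 0:(n_samp - 1L)
  ph <- template$phases_deg * pi / 180
  s <- rep(template$baseline, n_samp)
  for (n in 1:10) {
    if (template$amplitudes[n] > 0) {
      s <- s + template$amplitudes[n] * cos(2 * pi * n * k / n_samp + ph[n])
    }
  }
  s
}

# draw one truncated log-normal beat interval with matched mean/CV
draw_rr <- function(rr_mean, rr_cv) {
  if (rr_cv == 0) return(rr_mean)
  sdlog <- sqrt(log(1 + rr_cv^2))
  meanlog <- log(rr_mean) - sdlog^2 / 2
  for (i in 1:100) {
    rr <- stats::rlnorm(1, meanlog, sdlog)
    if (rr >= 0.33 && rr <= 1.5) return(rr)
  }
  rr_mean
}

#' Simulate one pulse recording
#'
#' Concatenates beats rendered from `template` with per-beat amplitude and
#' phase perturbations drawn from `jitter`, then adds white noise. Beats join
#' foot-to-foot (the template is assumed foot-aligned), so the true beat
#' boundaries are exact sample indices; they are stored in the recording's
#' `truth` attribute together with the drawn per-beat harmonic amplitudes and
#' phases, and can be recovered with [true_beatset()].
#'
#' @param template a `beat_template` (use [align_template_foot()] first if it
#'   was constructed by hand).
#' @param jitter a `jitter_model`.
#' @param duration_s recording length in seconds (must exceed 3 beat
#'   intervals; beats are appended while they fit).
#' @param fs sampling rate, Hz.
#' @param subject_id,session,channel identifiers carried in the recording.
#' @param seed overrides `jitter$seed`.
#' @return A `pulse_recording`.
#' @export
simulate_recording <- function(template, jitter, duration_s = 60, fs = 500,
                               subject_id = "S1", session = "M0",
                               channel = "BPW", seed = jitter$seed) {
  if (!is.finite(duration_s) || duration_s <= 3 * jitter$rr_mean) {
    abort_pv("pulsevar_invalid_parameter",
             "duration_s must exceed 3 * rr_mean = %.2f s", 3 * jitter$rr_mean)
  }
  with_local_seed(seed, {
    beats <- list()
    rr_s <- numeric(0)
    amp_mat <- NULL
    ph_mat <- NULL
    total <- 0
    repeat {
      rr <- draw_rr(jitter$rr_mean, jitter$rr_cv)
      n_samp <- round(fs * rr)
      rr_real <- n_samp / fs
      if (total + rr_real > duration_s + 1e-9) break
      amps <- pmax(template$amplitudes * (1 + stats::rnorm(10, 0, jitter$amp_jitter_cv)), 0)
      if (amps[1] == 0) amps[1] <- template$amplitudes[1] * 1e-3
      phs <- wrap_deg(template$phases_deg + stats::rnorm(10, 0, jitter$phase_jitter_sd))
      tpl_b <- beat_template(amps, phs, template$baseline)
      beats[[length(beats) + 1L]] <- render_beat(tpl_b, rr_real, fs)
      rr_s <- c(rr_s, rr_real)
      amp_mat <- rbind(amp_mat, amps)
      ph_mat <- rbind(ph_mat, phs)
      total <- total + rr_real
    }
    if (length(beats) < 3L) {
      abort_pv("pulsevar_insufficient_beats",
               "only %d beats fit in %.1f s", length(beats), duration_s)
    }
    samples <- unlist(beats, use.names = FALSE)
    if (jitter$noise_sd > 0) {
      samples <- samples + stats::rnorm(length(samples), 0, jitter$noise_sd)
    }
    n_per_beat <- vapply(beats, length, integer(1))
    rec <- pulse_recording(samples, fs, channel = channel,
                           subject_id = subject_id, session = session)
    attr(rec, "truth") <- list(
      rr_s = rr_s,
      start_index = c(0L, cumsum(n_per_beat)),  # 0-based beat boundaries incl. end
      amplitudes = unname(amp_mat),
      phases_deg = unname(ph_mat),
      template = template
    )
    rec
  })
}

#' Pulse recording container
#'
#' @param samples numeric vector of waveform samples (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param channel `"BPW"` (radial pressure) or `"PPG"` (optical).
#' @param subject_id,session identifiers; sessions are `"M0"` (pre) and
#'   `"M1"` (post).
#' @return An object of class `pulse_recording`.
#' @export
pulse_recording <- function(samples, fs, channel = c("BPW", "PPG"),
                            subject_id = "S1", session = c("M0", "M1")) {
  channel <- match.arg(channel)
  session <- match.arg(session)
  if (!is.finite(fs) || fs <= 0) {
    abort_pv("pulsevar_invalid_parameter", "fs must be > 0")
  }
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) {
    abort_pv("pulsevar_invalid_parameter", "samples must be finite")
  }
  if (length(samples) < 3 * fs) {
    abort_pv("pulsevar_invalid_parameter", "recording must be at least 3 s long")
  }
  structure(
    list(samples = samples, fs = fs, channel = channel,
         subject_id = subject_id, session = session),
    class = "pulse_recording"
  )
}

#' @export
print.pulse_recording <- function(x, ...) {
  cat(sprintf("<pulse_recording> %s %s %s: %.1f s @ %g Hz (%d samples)\n",
              x$subject_id, x$session, x$channel,
              length(x$samples) / x$fs, x$fs, length(x$samples)))
  invisible(x)
}

#' Ground-truth beat segmentation of a simulated recording
#'
#' Rebuilds a [beat_set] from the exact beat boundaries stored by
#' [simulate_recording()], bypassing foot detection. Used to validate the
#' harmonic round trip independently of the detector. The end of the last
#' beat counts as a boundary, so all simulated beats are segmented.
#'
#' @param rec a simulated `pulse_recording`.
#' @return A `beat_set`.
#' @export
true_beatset <- function(rec) {
  truth <- attr(rec, "truth")
  if (is.null(truth)) {
    abort_pv("pulsevar_invalid_parameter",
             "recording carries no simulation ground truth")
  }
  new_beat_set(foot_pos = as.numeric(truth$start_index), rec = rec,
               reject_outliers = FALSE)
}

#' Cohort specification for the synthetic-data generator
#'
#' Describes a cohort of subjects measured before (M0) and about a week after
#' (M1) an exposure, split into groups N (no side effects), C (cardiac-only)
#' and V (vascular-only); the pooled side-effect group CV is C plus V. The
#' vascular condition is emulated at M1 by inflating the per-beat phase
#' jitter across all ten harmonics and the amplitudes of harmonics 6-10;
#' group C receives only a small heart-rate-level shift, group N none.
#'
#' @param n_per_group named counts for groups N, C, V (defaults are the
#'   cohort sizes of the motivating study: 28, 34, 11).
#' @param effect_post_phase_sd multiplicative factor on `phase_jitter_sd` at
#'   M1 for group V (>= 1 reproduces the reported direction).
#' @param effect_post_high_harmonics multiplicative factor on the amplitudes
#'   of harmonics 6-10 at M1 for group V.
#' @param comorbidity_flag_prob probability a subject carries the
#'   comorbidity flag (subgroup A: hypertension/hyperlipidemia/hyperglycemia).
#' @param duration_s,fs recording length (s) and sampling rate (Hz).
#' @param rr_bpm_range per-subject resting heart-rate range (uniform draw).
#' @param rr_cv_range per-subject beat-interval CV range (uniform draw;
#'   default centred on 4 percent, the reported HR_CV level).
#' @param amp_jitter_cv,phase_jitter_sd,noise_sd baseline jitter parameters
#'   shared by all subjects (see [jitter_model()]).
#' @param base_template the canonical beat shape; each subject gets a mildly
#'   perturbed, re-foot-aligned copy.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(N = 28, C = 34, V = 11),
                        effect_post_phase_sd = 2,
                        effect_post_high_harmonics = 1.3,
                        comorbidity_flag_prob = 0.4,
                        duration_s = 60, fs = 500,
                        rr_bpm_range = c(60, 100),
                        rr_cv_range = c(0.025, 0.055),
                        amp_jitter_cv = 0.05,
                        phase_jitter_sd = 5,
                        noise_sd = 0.01,
                        base_template = default_beat_template()) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("N", "C", "V"))) {
    abort_pv("pulsevar_invalid_parameter",
             "n_per_group must be named with groups N, C, V")
  }
  ng <- c(N = 0, C = 0, V = 0)
  ng[names(n_per_group)] <- n_per_group
  if (any(ng < 0)) abort_pv("pulsevar_invalid_parameter", "group counts must be >= 0")
  if (effect_post_phase_sd < 1 || effect_post_high_harmonics < 1) {
    abort_pv("pulsevar_invalid_parameter", "effect factors must be >= 1")
  }
  structure(
    list(n_per_group = ng,
         effect_post_phase_sd = effect_post_phase_sd,
         effect_post_high_harmonics = effect_post_high_harmonics,
         comorbidity_flag_prob = comorbidity_flag_prob,
         duration_s = duration_s, fs = fs,
         rr_bpm_range = rr_bpm_range, rr_cv_range = rr_cv_range,
         amp_jitter_cv = amp_jitter_cv, phase_jitter_sd = phase_jitter_sd,
         noise_sd = noise_sd, base_template = base_template),
    class = "cohort_spec"
  )
}

#' Simulate a paired-measurement cohort
#'
#' Generates one M0 and one M1 recording per subject under a single seeded
#' RNG stream (identical `seed` reproduces the cohort bit-for-bit). Group V
#' subjects receive the vascular post-exposure perturbation at M1; group C a
#' heart-rate-level shift only; group N none, so with both effect factors at
#' 1 the two sessions are statistically exchangeable for every group.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed.
#' @return A list of class `pulse_cohort` with elements `recordings` (named
#'   list, `"<subject>_<session>"`) and `labels` (data.frame with columns
#'   subject, group, cv_flag, subgroup_AB).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  with_local_seed(seed, {
    groups <- rep(c("N", "C", "V"), times = spec$n_per_group[c("N", "C", "V")])
    n_subj <- length(groups)
    subjects <- sprintf("S%03d", seq_len(n_subj))
    recordings <- vector("list", 2L * n_subj)
    rec_names <- character(2L * n_subj)
    labels <- data.frame(
      subject = subjects, group = groups,
      cv_flag = groups %in% c("C", "V"),
      subgroup_AB = ifelse(stats::runif(n_subj) < spec$comorbidity_flag_prob, "A", "B"),
      stringsAsFactors = FALSE
    )
    base <- spec$base_template
    for (i in seq_len(n_subj)) {
      rr_mean <- 60 / stats::runif(1, spec$rr_bpm_range[1], spec$rr_bpm_range[2])
      rr_cv <- stats::runif(1, spec$rr_cv_range[1], spec$rr_cv_range[2])
      amps <- base$amplitudes * exp(stats::rnorm(10, 0, 0.08))
      phs <- wrap_deg(base$phases_deg + stats::runif(10, -10, 10))
      tpl <- align_template_foot(beat_template(amps, phs, base$baseline))

      jit0 <- jitter_model(rr_mean, rr_cv, spec$amp_jitter_cv,
                           spec$phase_jitter_sd, spec$noise_sd)
      m0 <- simulate_recording(tpl, jit0, spec$duration_s, spec$fs,
                               subject_id = subjects[i], session = "M0")

      tpl1 <- tpl
      jit1 <- jit0
      if (groups[i] == "V") {
        jit1 <- jitter_model(rr_mean, rr_cv, spec$amp_jitter_cv,
                             spec$phase_jitter_sd * spec$effect_post_phase_sd,
                             spec$noise_sd)
        amps1 <- tpl$amplitudes
        amps1[6:10] <- amps1[6:10] * spec$effect_post_high_harmonics
        tpl1 <- align_template_foot(beat_template(amps1, tpl$phases_deg, tpl$baseline))
      } else if (groups[i] == "C") {
        jit1 <- jitter_model(rr_mean * exp(stats::rnorm(1, 0, 0.02)), rr_cv,
                             spec$amp_jitter_cv, spec$phase_jitter_sd,
                             spec$noise_sd)
      }
      m1 <- simulate_recording(tpl1, jit1, spec$duration_s, spec$fs,
                               subject_id = subjects[i], session = "M1")

      recordings[[2L * i - 1L]] <- m0
      recordings[[2L * i]] <- m1
      rec_names[2L * i - 1L] <- paste0(subjects[i], "_M0")
      rec_names[2L * i] <- paste0(subjects[i], "_M1")
    }
    names(recordings) <- rec_names
    structure(list(recordings = recordings, labels = labels),
              class = "pulse_cohort")
  })
}

#' @export
print.pulse_cohort <- function(x, ...) {
  cat(sprintf("<pulse_cohort> %d subjects (%s), %d recordings\n",
              nrow(x$labels),
              paste(names(table(x$labels$group)), table(x$labels$group),
                    sep = "=", collapse = " "),
              length(x$recordings)))
  invisible(x)
}
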