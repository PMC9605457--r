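# shared fixtures: everything is generated in code, no stored data

# a template with only the fundamental
mono_template <- function(amp = 1, phase = 0, baseline = 0) {
  beat_template(c(amp, rep(0, 9)), c(phase, rep(0, 9)), baseline)
}

# two nonzero harmonics, known closed-form coefficients
duo_template <- function() {
  beat_template(c(2, 1, rep(0, 8)), c(0, 90, rep(0, 8)))
}

# fast, small recording for pipeline tests
quick_recording <- function(seed = 1, rr_cv = 0.04, amp_cv = 0.05,
                            phase_sd = 5, noise = 0.01, duration = 20,
                            fs = 250, rr_mean = 0.75) {
  simulate_recording(default_beat_template(),
                     jitter_model(rr_mean, rr_cv, amp_cv, phase_sd, noise,
                                  seed = seed),
                     duration_s = duration, fs = fs)
}

# direct DFT at one frequency: independent oracle for harmonic extraction
oracle_dft <- function(x, freq_hz, fs) {
  t <- (seq_along(x) - 1) / fs
  z <- sum(x * exp(-2i * pi * freq_hz * t))
  2 * z / length(x)
}

# brute-force AUC over all positive/negative pairs (ties half)
oracle_auc <- function(scores, labels) {
  p <- scores[labels == 1]
  q <- scores[labels == 0]
  s <- 0
  for (a in p) for (b in q) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(p) * length(q))
}

# local angle wrap for assertions (independent of package internals)
wrap_deg_test <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}
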