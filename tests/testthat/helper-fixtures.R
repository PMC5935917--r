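# Shared fixtures built in code at test time.

# A beat series with one beat per second and the given PWAs, peaks at
# foot + 0.3 s, starting at `start`.
make_beats <- function(pwa, start = 0) {
  foot <- start + seq_along(pwa) - 1
  rhpav:::beat_series(foot_s = foot, peak_s = foot + 0.3, pwa = pwa,
                      flag = rep(FALSE, length(pwa)))
}

# Beat series whose window means are fully controlled: `values` is a named
# list window-name -> mean PWA; each window gets `n` identical beats.
beats_with_window_means <- function(windows, values, n = 20) {
  pwa <- numeric(0); foot <- numeric(0)
  for (w in names(values)) {
    t0 <- windows[[w]]["start"]
    len <- windows[[w]]["length"]
    ts <- t0 + (seq_len(n) - 0.5) * len / n
    foot <- c(foot, ts - 0.3)
    pwa <- c(pwa, rep(values[[w]], n))
  }
  o <- order(foot)
  rhpav:::beat_series(foot_s = foot[o], peak_s = foot[o] + 0.3,
                      pwa = pwa[o], flag = rep(FALSE, length(foot)))
}

# Window set matching the default protocol timeline.
default_windows <- function(timeline = protocol_timeline()) {
  list(baseline = c(start = timeline$t_baseline_start + 40, length = 40),
       hyperemia = c(start = timeline$t_cuff_deflate + 40, length = 40))
}

# Noise-free pulse train signal (volume polarity) for beat-count oracles.
clean_train <- function(bpm = 60, duration = 40, fs = 100, amp = 1) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  amp * rhpav:::pulse_shape(t * bpm / 60)
}
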