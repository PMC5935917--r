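#' Condition a raw PPG channel
#'
#' Normalizes polarity so that a volume increase is positive (transmission
#' PPG records intensity, which moves opposite to volume), removes baseline
#' wander with a 0.3 Hz second-order Butterworth high-pass, and limits the
#' band to the cardiac range with a 10 Hz fourth-order low-pass. Both
#' filters are applied forward-backward ([signal::filtfilt()]) so beat
#' timing is not shifted and the 40-s window semantics downstream are
#' preserved.
#'
#' @param x numeric signal vector, uniformly sampled.
#' @param sampling_rate sampling rate (Hz); must exceed twice the low-pass
#'   corner.
#' @param polarity `"positive"` (signal already follows volume) or
#'   `"inverted"` (intensity-like: volume increase lowers the signal).
#' @param highpass_hz,lowpass_hz filter corners (Hz).
#' @return Conditioned numeric vector, zero-centred, volume-positive.
#' @export
preprocess_ppg <- function(x, sampling_rate, polarity = c("positive", "inverted"),
                           highpass_hz = 0.3, lowpass_hz = 10) {
  polarity <- match.arg(polarity)
  if (sampling_rate < 2 * lowpass_hz) {
    stop("sampling rate (", sampling_rate, " Hz) below twice the low-pass corner")
  }
  if (polarity == "inverted") x <- -x
  x <- x - mean(x)
  hp <- signal::butter(2, highpass_hz / (sampling_rate / 2), type = "high")
  lp <- signal::butter(4, lowpass_hz / (sampling_rate / 2), type = "low")
  # odd-reflection padding suppresses filtfilt edge transients, which would
  # otherwise dwarf the pulse near the record ends
  n <- length(x)
  pad <- min(n - 1, round(3 * sampling_rate / highpass_hz))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(hp, xp)
  y <- signal::filtfilt(lp, y)
  y[(pad + 1):(pad + n)]
}

#' Detect beats and pulse-wave amplitudes
#'
#' Segments a conditioned PPG channel into beats. Candidate peaks are local
#' maxima; each is accepted if its foot-to-peak amplitude exceeds an
#' adaptive prominence threshold equal to 20% of the median pulse-wave
#' amplitude (PWA) of beats accepted in the preceding 60 s (falling back to
#' the median of all accepted beats, with an absolute noise-derived floor
#' before any beat exists). The foot of each beat is the signal minimum
#' between the previous accepted peak and the current peak (looking back at
#' most 2 s). Candidates closer than `min_ibi` to the previous accepted
#' peak replace it if taller, otherwise are dropped. Epochs with no
#' suprathreshold pulsation - e.g. the occluded arm - simply yield no
#' beats.
#'
#' @param x conditioned signal from [preprocess_ppg()].
#' @param sampling_rate sampling rate (Hz).
#' @param min_ibi,max_ibi physiological inter-beat-interval bounds (s);
#'   beats whose interval to the previous beat falls outside are flagged,
#'   not dropped.
#' @param prominence_frac adaptive threshold as a fraction of the recent
#'   median PWA (default 0.2).
#' @param history_s length of the trailing window for the adaptive median
#'   (s).
#' @return A `beat_series`: data.frame with columns `foot_s`, `peak_s`,
#'   `pwa`, `flag` (logical, TRUE when the inter-beat interval is
#'   non-physiological). Zero rows is a valid result.
#' @export
detect_beats <- function(x, sampling_rate, min_ibi = 0.3, max_ibi = 2.0,
                         prominence_frac = 0.2, history_s = 60) {
  n <- length(x)
  empty <- beat_series(numeric(0), numeric(0), numeric(0), logical(0))
  if (n < 3) return(empty)
  dx <- diff(x)
  cand <- which(dx[-(n - 1)] > 0 & dx[-1] <= 0) + 1
  if (!length(cand)) return(empty)

  # absolute floor from the sample-to-sample variation of the whole record;
  # only governs acceptance before any beat exists
  noise_floor <- 5 * stats::mad(dx)
  if (noise_floor == 0) noise_floor <- .Machine$double.eps

  lookback <- round(2 * sampling_rate)
  min_gap <- min_ibi * sampling_rate
  peak_i <- integer(0); foot_i <- integer(0); pwa <- numeric(0)

  for (p in cand) {
    last <- if (length(peak_i)) peak_i[length(peak_i)] else NA_integer_
    lo <- if (is.na(last)) max(1L, p - lookback) else max(last, p - lookback)
    if (lo >= p) next
    f <- lo - 1L + which.min(x[lo:p])
    if (f == p) next
    a <- x[p] - x[f]

    if (!length(pwa)) {
      thr <- noise_floor
    } else {
      recent <- pwa[(p - peak_i) / sampling_rate <= history_s]
      thr <- prominence_frac *
        stats::median(if (length(recent) >= 3) recent else pwa)
    }
    if (a <= thr) next

    if (!is.na(last) && (p - last) < min_gap) {
      if (x[p] > x[last]) {
        # replace the previous (smaller) peak with this one
        prev <- if (length(peak_i) > 1) peak_i[length(peak_i) - 1] else NA_integer_
        lo2 <- if (is.na(prev)) max(1L, p - lookback) else max(prev, p - lookback)
        f2 <- lo2 - 1L + which.min(x[lo2:p])
        k <- length(peak_i)
        peak_i[k] <- p; foot_i[k] <- f2; pwa[k] <- x[p] - x[f2]
      }
      next
    }
    peak_i <- c(peak_i, p); foot_i <- c(foot_i, f); pwa <- c(pwa, a)
  }

  if (!length(peak_i)) return(empty)
  peak_s <- (peak_i - 1) / sampling_rate
  foot_s <- (foot_i - 1) / sampling_rate
  ibi <- c(NA, diff(peak_s))
  flag <- !is.na(ibi) & (ibi < min_ibi | ibi > max_ibi)
  beat_series(foot_s, peak_s, pwa, flag)
}

beat_series <- function(foot_s, peak_s, pwa, flag) {
  structure(data.frame(foot_s = foot_s, peak_s = peak_s, pwa = pwa,
                       flag = flag),
            class = c("beat_series", "data.frame"))
}

#' Mean pulse-wave amplitude over a time window
#'
#' Averages the PWA of beats whose PEAK time lies in the half-open window
#' `[window_start, window_start + window_length)`. The beat count is
#' returned for quality control; zero beats yields `mean_pwa = NA` and it
#' is the caller's decision whether that is an error.
#'
#' @param beats a `beat_series` from [detect_beats()].
#' @param window_start window start (s).
#' @param window_length window length (s), > 0.
#' @return List with `mean_pwa` and `n_beats`.
#' @examples
#' b <- detect_beats(sin(2 * pi * seq(0, 10, by = 0.01)), 100)
#' window_mean_pwa(b, 2, 4)
#' @export
window_mean_pwa <- function(beats, window_start, window_length) {
  stopifnot(window_length > 0)
  sel <- beats$peak_s >= window_start & beats$peak_s < window_start + window_length
  n <- sum(sel)
  list(mean_pwa = if (n) mean(beats$pwa[sel]) else NA_real_, n_beats = n)
}

#' Write / read a beat series as CSV
#'
#' Columns `foot_s`, `peak_s`, `pwa`, `flag`.
#'
#' @param beats a `beat_series`.
#' @param path CSV path.
#' @return `write_beat_series` invisibly returns `path`;
#'   `read_beat_series` returns a `beat_series`.
#' @export
write_beat_series <- function(beats, path) {
  data.table::fwrite(as.data.frame(beats), path)
  invisible(path)
}

#' @rdname write_beat_series
#' @export
read_beat_series <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  beat_series(d$foot_s, d$peak_s, d$pwa, as.logical(d$flag))
}
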