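#' Reactive-hyperemia PAV index
#'
#' Computes the RH-PAV index from per-beat series of the test (cuffed) and
#' contralateral control arms. Per arm, the hyperemia-to-baseline ratio is
#' the mean pulse-wave amplitude in the 40-s window beginning 40 s after
#' cuff deflation divided by the mean PWA in the 40-s window beginning 40 s
#' after the start of the pre-occlusion baseline. The index is the test-arm
#' ratio divided by the control-arm ratio; the contralateral division
#' cancels any systemic amplitude change common to both arms.
#'
#' @param test_beats,control_beats `beat_series` objects for the two arms
#'   (from [detect_beats()]).
#' @param timeline a [event_timeline()] with at least the baseline start
#'   and cuff deflation events.
#' @param baseline_offset,hyperemia_offset window offsets (s) from the
#'   baseline start and the deflation instant; 40 s by protocol.
#' @param window_length window length (s); 40 s by protocol.
#' @param min_beats minimum beats required in every window (default 10);
#'   fewer is a QC failure naming the offending window.
#' @return A `pav_result`: list with per-arm window means and beat counts,
#'   `ratio_test`, `ratio_control`, `rh_pav = ratio_test / ratio_control`,
#'   and the window definitions used.
#' @examples
#' rec <- simulate_session(subject_params(hyperemia_gain = 1.4), seed = 7)
#' res <- analyze_recording(rec)
#' res$rh_pav
#' @export
compute_rh_pav <- function(test_beats, control_beats, timeline,
                           baseline_offset = 40, hyperemia_offset = 40,
                           window_length = 40, min_beats = 10) {
  stopifnot(inherits(timeline, "ppg_timeline"))
  windows <- list(
    baseline = c(start = timeline$t_baseline_start + baseline_offset,
                 length = window_length),
    hyperemia = c(start = timeline$t_cuff_deflate + hyperemia_offset,
                  length = window_length)
  )
  m <- list()
  for (arm in c("test", "control")) {
    beats <- if (arm == "test") test_beats else control_beats
    for (w in names(windows)) {
      res <- window_mean_pwa(beats, windows[[w]]["start"], windows[[w]]["length"])
      if (res$n_beats < min_beats) {
        stop("QC failure: only ", res$n_beats, " beats in the ", arm,
             "-arm ", w, " window (need >= ", min_beats, ")")
      }
      m[[paste(arm, w, sep = "_")]] <- res
    }
  }
  ratio_test <- m$test_hyperemia$mean_pwa / m$test_baseline$mean_pwa
  ratio_control <- m$control_hyperemia$mean_pwa / m$control_baseline$mean_pwa
  structure(list(
    baseline_mean = c(test = m$test_baseline$mean_pwa,
                      control = m$control_baseline$mean_pwa),
    hyperemia_mean = c(test = m$test_hyperemia$mean_pwa,
                       control = m$control_hyperemia$mean_pwa),
    n_beats = c(test_baseline = m$test_baseline$n_beats,
                test_hyperemia = m$test_hyperemia$n_beats,
                control_baseline = m$control_baseline$n_beats,
                control_hyperemia = m$control_hyperemia$n_beats),
    ratio_test = ratio_test,
    ratio_control = ratio_control,
    rh_pav = ratio_test / ratio_control,
    windows = windows
  ), class = "pav_result")
}

#' Nitroglycerin PAV index
#'
#' Ratio of the mean test-arm PWA in the 40-s window beginning 3 min after
#' nitroglycerin administration to the mean PWA in the 40-s window
#' beginning 40 s after the start of the second baseline. No contralateral
#' correction is applied.
#'
#' @param test_beats `beat_series` for the test arm.
#' @param timeline a [event_timeline()] carrying `t_second_baseline_start`
#'   and `t_ntg`.
#' @param baseline_offset offset (s) of the second-baseline window.
#' @param ntg_offset offset (s) of the post-NTG window (180 s by protocol).
#' @param window_length window length (s).
#' @param min_beats minimum beats per window.
#' @return A `ntg_pav_result` with the two window means, beat counts and
#'   `ntg_pav`.
#' @export
compute_ntg_pav <- function(test_beats, timeline, baseline_offset = 40,
                            ntg_offset = 180, window_length = 40,
                            min_beats = 10) {
  stopifnot(inherits(timeline, "ppg_timeline"))
  if (is.null(timeline$t_ntg) || is.null(timeline$t_second_baseline_start)) {
    stop("protocol error: timeline lacks the NTG / second-baseline events")
  }
  windows <- list(
    second_baseline = c(start = timeline$t_second_baseline_start + baseline_offset,
                        length = window_length),
    post_ntg = c(start = timeline$t_ntg + ntg_offset, length = window_length)
  )
  m <- list()
  for (w in names(windows)) {
    res <- window_mean_pwa(test_beats, windows[[w]]["start"], windows[[w]]["length"])
    if (res$n_beats < min_beats) {
      stop("QC failure: only ", res$n_beats, " beats in the ", w,
           " window (need >= ", min_beats, ")")
    }
    m[[w]] <- res
  }
  structure(list(
    second_baseline_mean = m$second_baseline$mean_pwa,
    post_ntg_mean = m$post_ntg$mean_pwa,
    n_beats = c(second_baseline = m$second_baseline$n_beats,
                post_ntg = m$post_ntg$n_beats),
    ntg_pav = m$post_ntg$mean_pwa / m$second_baseline$mean_pwa,
    windows = windows
  ), class = "ntg_pav_result")
}

#' Flow-mediated dilation percent change
#'
#' `%FMD = (max(post) - baseline) / baseline * 100`, where the post list
#' holds the brachial diameters measured after cuff deflation (by protocol
#' at 1, 2 and 3 min). The same arithmetic with post-nitroglycerin
#' diameters gives %NMD.
#'
#' @param baseline_diameter baseline brachial diameter (mm, > 0).
#' @param post_diameters non-empty vector of post-deflation diameters (mm,
#'   > 0).
#' @return An `fmd_result` with `baseline_diameter`, `max_diameter` and
#'   `fmd_percent`.
#' @examples
#' compute_fmd_percent(4.0, c(4.1, 4.4, 4.2))$fmd_percent  # 10
#' @export
compute_fmd_percent <- function(baseline_diameter, post_diameters) {
  if (!length(post_diameters)) stop("post-deflation diameter list is empty")
  if (baseline_diameter <= 0 || any(post_diameters <= 0)) {
    stop("non-positive arterial diameter rejected")
  }
  mx <- max(post_diameters)
  structure(list(
    baseline_diameter = baseline_diameter,
    max_diameter = mx,
    fmd_percent = (mx - baseline_diameter) / baseline_diameter * 100
  ), class = "fmd_result")
}

#' Full waveform-to-index analysis of a recording
#'
#' Conditions both channels, detects beats, and computes RH-PAV (and, when
#' the timeline carries the NTG events, NTG-PAV).
#'
#' @param recording a `ppg_recording` (simulated or read from disk).
#' @param timeline optional [event_timeline()] overriding the one stored in
#'   the recording.
#' @param ... passed to [compute_rh_pav()].
#' @return The `pav_result`, with the `ntg_pav_result` attached as element
#'   `ntg` when computable, plus the two `beat_series` as `beats`.
#' @export
analyze_recording <- function(recording, timeline = NULL, ...) {
  stopifnot(inherits(recording, "ppg_recording"))
  if (is.null(timeline)) timeline <- recording$timeline
  fs <- recording$sampling_rate
  pol <- recording$polarity
  test <- preprocess_ppg(recording$signals$test_arm, fs, pol)
  ctrl <- preprocess_ppg(recording$signals$control_arm, fs, pol)
  tb <- detect_beats(test, fs)
  cb <- detect_beats(ctrl, fs)
  res <- compute_rh_pav(tb, cb, timeline, ...)
  if (!is.null(timeline$t_ntg)) res$ntg <- compute_ntg_pav(tb, timeline)
  res$beats <- list(test = tb, control = cb)
  res
}

#' @export
print.pav_result <- function(x, ...) {
  cat("RH-PAV result\n")
  cat(sprintf("  test arm:    baseline %.4g, hyperemia %.4g, ratio %.3f\n",
              x$baseline_mean["test"], x$hyperemia_mean["test"], x$ratio_test))
  cat(sprintf("  control arm: baseline %.4g, hyperemia %.4g, ratio %.3f\n",
              x$baseline_mean["control"], x$hyperemia_mean["control"],
              x$ratio_control))
  cat(sprintf("  RH-PAV (contralaterally normalized): %.3f\n", x$rh_pav))
  if (!is.null(x$ntg)) {
    cat(sprintf("  NTG-PAV: %.3f\n", x$ntg$ntg_pav))
  }
  invisible(x)
}
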