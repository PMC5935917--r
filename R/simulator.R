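#' Subject-level physiological parameters for a simulated session
#'
#' The programmed hyperemia gain `hyperemia_gain` (g_h) is the ground truth
#' the analysis pipeline must recover as RH-PAV. `drift_gain` (g_s) is a
#' slow multiplicative amplitude trend applied to BOTH arms, emulating the
#' systemic changes that contralateral normalization is designed to cancel.
#' `ntg_gain` (g_n) multiplies both arms after nitroglycerin.
#'
#' @param heart_rate beats per minute (> 0).
#' @param amp_test,amp_control baseline pulsatile arterial volume amplitude
#'   per arm (arbitrary volume, i.e. concentration x path, units).
#' @param hyperemia_gain dimensionless test-arm amplitude gain reached
#'   during the post-deflation plateau (> 0).
#' @param drift_gain dimensionless systemic gain reached by the hyperemia
#'   measurement window, applied to both arms (> 0).
#' @param ntg_gain dimensionless gain applied to both arms after NTG (> 0).
#' @param onset_delay_s,onset_scale_s delay and steepness (s) of the
#'   logistic hyperemia onset after cuff deflation.
#' @param plateau_s time after deflation (s) at which the hyperemic plateau
#'   ends and exponential decay begins; must exceed 80 s so the plateau
#'   covers the measurement window 40-80 s post-deflation.
#' @param decay_tau_s exponential decay constant (s) of the hyperemic gain
#'   after the plateau.
#' @param spo2 arterial oxygen saturation in `[0, 1]`.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(heart_rate = 70, amp_test = 0.02, amp_control = 0.02,
                           hyperemia_gain = 1.4, drift_gain = 1, ntg_gain = 1.5,
                           onset_delay_s = 10, onset_scale_s = 2,
                           plateau_s = 90, decay_tau_s = 40, spo2 = 0.97) {
  stopifnot(heart_rate > 0, amp_test > 0, amp_control > 0,
            hyperemia_gain > 0, drift_gain > 0, ntg_gain > 0,
            onset_delay_s >= 0, onset_scale_s > 0,
            plateau_s > 80, decay_tau_s > 0, spo2 >= 0, spo2 <= 1)
  structure(as.list(environment()), class = "subject_params")
}

#' Optical parameters of the Beer-Lambert finger model
#'
#' Single-wavelength (nominally 940 nm infrared LED, transmission mode)
#' Beer-Lambert model of the finger: detected intensity
#' `I(t) = I0 * exp(-eps_eff * c * (d_static + d_venous(t) + d(t)))` where
#' `d(t)` is the pulsatile arterial path, `d_static` the non-pulsatile
#' tissue/venous path, and `d_venous(t)` a slowly-varying venous pooling
#' increment present only while the cuff is inflated. The effective molar
#' absorptivity mixes oxy- and deoxyhemoglobin by arterial saturation.
#' Absorptivities are on an arbitrary relative scale: the RH-PAV index is
#' a ratio, so only products eps * c * d matter.
#'
#' @param i0 source intensity (> 0, arbitrary units).
#' @param eps_hbo2,eps_hb molar absorptivities of oxygenated and
#'   deoxygenated hemoglobin (per unit concentration x path, > 0).
#' @param hb_conc hemoglobin concentration (arbitrary units, > 0).
#' @param d_static static (non-pulsatile) optical path (>= 0).
#' @param venous_path venous pooling path increment during occlusion (>= 0).
#' @return An object of class `optical_params`.
#' @export
optical_params <- function(i0 = 1, eps_hbo2 = 1.1, eps_hb = 0.8, hb_conc = 1,
                           d_static = 1, venous_path = 0.2) {
  stopifnot(i0 > 0, eps_hbo2 > 0, eps_hb > 0, hb_conc > 0,
            d_static >= 0, venous_path >= 0)
  structure(as.list(environment()), class = "optical_params")
}

#' Additive noise model for simulated recordings
#'
#' White measurement noise plus sinusoidal baseline wander (respiratory /
#' vasomotor band). Amplitudes may be given in absolute signal (intensity)
#' units or, more conveniently, as fractions of the nominal AC (pulsatile)
#' intensity amplitude of the session, resolved at simulation time.
#'
#' @param sd white-noise standard deviation in signal units, or `NA` to use
#'   `sd_frac_ac`.
#' @param sd_frac_ac white-noise SD as a fraction of the nominal AC
#'   amplitude (default 0.02, i.e. 2% noise).
#' @param wander_amplitude baseline-wander amplitude in signal units, or
#'   `NA` to use `wander_frac_ac`.
#' @param wander_frac_ac wander amplitude as a fraction of the nominal AC
#'   amplitude (default 2: wander twice the pulse, removed by filtering).
#' @param wander_freq wander frequency (Hz), default 0.05.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = NA, sd_frac_ac = 0.02,
                        wander_amplitude = NA, wander_frac_ac = 2,
                        wander_freq = 0.05) {
  stopifnot(is.na(sd) || sd >= 0, sd_frac_ac >= 0,
            is.na(wander_amplitude) || wander_amplitude >= 0,
            wander_frac_ac >= 0, wander_freq >= 0)
  structure(as.list(environment()), class = "noise_model")
}

# clamp x/1 ramp to [0, 1]
ramp01 <- function(x) pmin(1, pmax(0, x))

#' Pulsatile arterial volume waveform for one arm
#'
#' Generates the noise-free arterial volume trace d(t) for the test or
#' control arm over the occlusion protocol: a cardiac pulse train at the
#' subject heart rate whose per-beat amplitude follows the protocol
#' envelope. The test-arm pulse is abolished during occlusion (the cuff is
#' suprasystolic) and, after deflation, rises with a delayed logistic onset
#' to `hyperemia_gain` times baseline, holds that plateau through the
#' measurement window, then decays exponentially. The control arm never
#' sees the cuff. The systemic drift gain ramps geometrically from 1 (end
#' of the baseline window) to `drift_gain` (start of the hyperemia window)
#' on BOTH arms, and the NTG gain ramps in over 2 min after `t_ntg` on both
#' arms.
#'
#' @param subject a [subject_params()] object.
#' @param timeline a [event_timeline()] object.
#' @param arm `"test"` (cuffed) or `"control"` (contralateral).
#' @param duration recording length (s); must cover the full timeline
#'   including measurement windows.
#' @param sampling_rate sampling rate (Hz), >= 50.
#' @param template a [pulse_template()] giving the cycle shape.
#' @return Numeric vector of arterial volume samples (volume units, >= 0).
#' @export
generate_pulse_train <- function(subject, timeline, arm = c("test", "control"),
                                 duration, sampling_rate = 100,
                                 template = pulse_template()) {
  arm <- match.arg(arm)
  stopifnot(inherits(subject, "subject_params"), inherits(timeline, "ppg_timeline"))
  if (sampling_rate < 50) stop("sampling rate must be at least 50 Hz")
  if (duration < timeline_end(timeline)) {
    stop("protocol error: duration (", duration, " s) does not cover the ",
         "protocol timeline (needs >= ", timeline_end(timeline), " s)")
  }
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  period <- 60 / subject$heart_rate
  pulse <- pulse_shape(t / period, template$upstroke_frac, template$decay_tau)

  env <- rep(1, n)
  if (arm == "test") {
    occluded <- t >= timeline$t_cuff_inflate & t < timeline$t_cuff_deflate
    env[occluded] <- 0
    tau <- t - timeline$t_cuff_deflate
    post <- tau >= 0
    onset <- stats::plogis((tau[post] - subject$onset_delay_s) / subject$onset_scale_s)
    decay <- exp(-pmax(0, tau[post] - subject$plateau_s) / subject$decay_tau_s)
    env[post] <- 1 + (subject$hyperemia_gain - 1) * onset * decay
  }
  # systemic drift: geometric ramp between the two measurement windows
  d0 <- timeline$t_baseline_start + 80
  d1 <- timeline$t_cuff_deflate + 40
  env <- env * subject$drift_gain^ramp01((t - d0) / (d1 - d0))
  if (!is.null(timeline$t_ntg)) {
    env <- env * subject$ntg_gain^ramp01((t - timeline$t_ntg) / 120)
  }
  amp <- if (arm == "test") subject$amp_test else subject$amp_control
  amp * env * pulse
}

#' Detected light intensity from an arterial volume waveform
#'
#' Applies the Beer-Lambert law: `I(t) = i0 * exp(-eps_eff * c *
#' (d_static + d_venous(t) + d(t)))`, with `eps_eff = s * eps_hbo2 +
#' (1 - s) * eps_hb`. Venous pooling adds a slowly-varying, non-pulsatile
#' path increment only where `occluded_mask` is true, ramped over
#' `venous_ramp_s` seconds at the mask edges. Volume increase means
#' intensity decrease (transmission-mode polarity).
#'
#' @param volume non-negative arterial volume waveform (from
#'   [generate_pulse_train()]).
#' @param optics an [optical_params()] object.
#' @param saturation arterial oxygen saturation in `[0, 1]`.
#' @param occluded_mask optional logical vector (same length) marking
#'   occluded samples.
#' @param sampling_rate sampling rate (Hz); required when `occluded_mask`
#'   is given.
#' @param venous_ramp_s ramp length (s) for venous pooling at occlusion
#'   onset/release.
#' @return Numeric intensity vector, in `(0, i0]`.
#' @export
beer_lambert_intensity <- function(volume, optics, saturation = 0.97,
                                   occluded_mask = NULL, sampling_rate = NULL,
                                   venous_ramp_s = 10) {
  stopifnot(inherits(optics, "optical_params"))
  if (any(volume < 0)) stop("negative arterial volume path rejected")
  if (saturation < 0 || saturation > 1) stop("saturation must be in [0, 1]")
  eps_eff <- saturation * optics$eps_hbo2 + (1 - saturation) * optics$eps_hb
  d_ven <- 0
  if (!is.null(occluded_mask) && any(occluded_mask)) {
    if (is.null(sampling_rate)) {
      stop("sampling_rate is required when occluded_mask is supplied")
    }
    d_ven <- optics$venous_path * ramp_mask(occluded_mask, sampling_rate, venous_ramp_s)
  }
  optics$i0 * exp(-eps_eff * optics$hb_conc * (optics$d_static + d_ven + volume))
}

# Smooth a logical mask into a 0..1 envelope with linear ramps of
# ramp_s seconds inside each contiguous TRUE run.
ramp_mask <- function(mask, sampling_rate, ramp_s) {
  out <- numeric(length(mask))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  w <- max(1, round(ramp_s * sampling_rate))
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    j <- seq_along(i)
    out[i] <- pmin(1, (j - 1) / w, (rev(j) - 1) / w)
  }
  out
}

#' Nominal AC intensity amplitude of a session
#'
#' The peak-to-foot intensity excursion produced by one baseline-amplitude
#' pulse on the test arm, used to express noise levels as fractions of the
#' pulsatile signal.
#'
#' @param subject a [subject_params()] object.
#' @param optics an [optical_params()] object.
#' @return Scalar intensity amplitude.
#' @export
nominal_ac_amplitude <- function(subject, optics) {
  eps_eff <- subject$spo2 * optics$eps_hbo2 + (1 - subject$spo2) * optics$eps_hb
  dc <- optics$i0 * exp(-eps_eff * optics$hb_conc * optics$d_static)
  dc * (1 - exp(-eps_eff * optics$hb_conc * subject$amp_test))
}

#' Simulate a complete two-channel PPG occlusion session
#'
#' Composes [generate_pulse_train()] and [beer_lambert_intensity()] for the
#' test and control arms, adds white noise and baseline wander, and returns
#' a two-channel recording together with the programmed ground truth. A
#' single seed streams to all stochastic components, so identical inputs
#' give bit-identical recordings.
#'
#' @param subject a [subject_params()] object.
#' @param optics an [optical_params()] object.
#' @param noise a [noise_model()] object.
#' @param timeline a [event_timeline()] object.
#' @param duration recording length (s); default covers the timeline plus
#'   10 s.
#' @param sampling_rate sampling rate (Hz), default 100.
#' @param seed optional integer seed; when given, the session is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @param template a [pulse_template()].
#' @return A `ppg_recording`: list with `sampling_rate`, `signals`
#'   (data.frame `time_s`, `test_arm`, `control_arm`), `units`
#'   (`"intensity"`), `polarity` (`"inverted"`), `timeline`, and
#'   `ground_truth` (`hyperemia_gain`, `drift_gain`, `ntg_gain`,
#'   `heart_rate`).
#' @examples
#' rec <- simulate_session(subject_params(hyperemia_gain = 1.4), seed = 1)
#' str(rec$ground_truth)
#' @export
simulate_session <- function(subject = subject_params(),
                             optics = optical_params(),
                             noise = noise_model(),
                             timeline = protocol_timeline(),
                             duration = NULL, sampling_rate = 100,
                             seed = NULL, template = pulse_template()) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(duration)) duration <- timeline_end(timeline) + 10
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  occluded <- t >= timeline$t_cuff_inflate & t < timeline$t_cuff_deflate

  vol_test <- generate_pulse_train(subject, timeline, "test", duration,
                                   sampling_rate, template)
  vol_ctrl <- generate_pulse_train(subject, timeline, "control", duration,
                                   sampling_rate, template)
  i_test <- beer_lambert_intensity(vol_test, optics, subject$spo2,
                                   occluded_mask = occluded,
                                   sampling_rate = sampling_rate)
  i_ctrl <- beer_lambert_intensity(vol_ctrl, optics, subject$spo2)

  ac <- nominal_ac_amplitude(subject, optics)
  sd <- if (is.na(noise$sd)) noise$sd_frac_ac * ac else noise$sd
  wa <- if (is.na(noise$wander_amplitude)) noise$wander_frac_ac * ac else noise$wander_amplitude
  for (ch in c("i_test", "i_ctrl")) {
    x <- get(ch)
    if (sd > 0) x <- x + stats::rnorm(n, sd = sd)
    if (wa > 0) {
      x <- x + wa * sin(2 * pi * noise$wander_freq * t + stats::runif(1, 0, 2 * pi))
    }
    assign(ch, x)
  }

  structure(list(
    sampling_rate = sampling_rate,
    signals = data.frame(time_s = t, test_arm = i_test, control_arm = i_ctrl),
    units = "intensity",
    polarity = "inverted",
    timeline = timeline,
    ground_truth = list(hyperemia_gain = subject$hyperemia_gain,
                        drift_gain = subject$drift_gain,
                        ntg_gain = subject$ntg_gain,
                        heart_rate = subject$heart_rate)
  ), class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("Two-channel PPG recording: %.1f s at %g Hz (%s, %s polarity)\n",
              nrow(x$signals) / x$sampling_rate, x$sampling_rate,
              x$units, x$polarity))
  print(x$timeline)
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  synthetic ground truth: g_h = %.3g, g_s = %.3g, g_n = %.3g\n",
                x$ground_truth$hyperemia_gain, x$ground_truth$drift_gain,
                x$ground_truth$ntg_gain))
  }
  invisible(x)
}
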