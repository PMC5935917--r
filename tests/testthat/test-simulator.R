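test_that("pulse template spans [0, 1] with a single global maximum", {
  tpl <- pulse_template(n = 200)
  expect_equal(min(tpl$samples), 0)
  expect_equal(max(tpl$samples), 1)
  expect_equal(sum(abs(tpl$samples - 1) < 1e-12), 1)
  expect_equal(which.min(tpl$samples), 1)  # foot at phase 0
})

test_that("identity gains leave window amplitudes equal and occlusion abolishes the test-arm pulse", {
  tl <- protocol_timeline()
  sub <- subject_params(heart_rate = 60, hyperemia_gain = 1, drift_gain = 1)
  v <- generate_pulse_train(sub, tl, "test", duration = 480, sampling_rate = 100)
  t <- (seq_along(v) - 1) / 100
  base_w <- t >= tl$t_baseline_start + 40 & t < tl$t_baseline_start + 80
  hyp_w <- t >= tl$t_cuff_deflate + 40 & t < tl$t_cuff_deflate + 80
  expect_equal(mean(v[hyp_w]), mean(v[base_w]), tolerance = 1e-3)
  occ <- t >= tl$t_cuff_inflate & t < tl$t_cuff_deflate
  expect_lt(max(v[occ]), 0.01 * max(v[base_w]))
})

test_that("programmed hyperemia gain appears exactly in the measurement window", {
  tl <- protocol_timeline()
  sub <- subject_params(heart_rate = 60, hyperemia_gain = 1.41)
  v <- generate_pulse_train(sub, tl, "test", duration = 480, sampling_rate = 100)
  t <- (seq_along(v) - 1) / 100
  base_w <- t >= tl$t_baseline_start + 40 & t < tl$t_baseline_start + 80
  hyp_w <- t >= tl$t_cuff_deflate + 40 & t < tl$t_cuff_deflate + 80
  expect_equal(mean(v[hyp_w]) / mean(v[base_w]), 1.41, tolerance = 0.01)
  # control arm is unaffected by the cuff
  vc <- generate_pulse_train(sub, tl, "control", duration = 480, sampling_rate = 100)
  expect_equal(mean(vc[hyp_w]) / mean(vc[base_w]), 1, tolerance = 1e-3)
})

test_that("too-short recordings and bad timelines are protocol errors", {
  expect_error(generate_pulse_train(subject_params(), protocol_timeline(),
                                    "test", duration = 100),
               "protocol error")
  expect_error(event_timeline(100, 50, 400), "strictly increasing")
  expect_error(event_timeline(5, 90, 390, t_second_baseline_start = 600),
               "given together")
})

test_that("Beer-Lambert intensity matches the law and its linearization", {
  opt <- optical_params(i0 = 2, eps_hbo2 = 1.1, eps_hb = 0.8, hb_conc = 1,
                        d_static = 1)
  s <- 0.97
  eps <- s * opt$eps_hbo2 + (1 - s) * opt$eps_hb
  # no pulsation, no venous increment -> flat at I0 * exp(-eps*c*d_static)
  i_flat <- beer_lambert_intensity(rep(0, 100), opt, s)
  expect_equal(i_flat, rep(2 * exp(-eps), 100))
  # log-ratio of max to min intensity recovers eps*c*delta_d exactly
  dd <- 0.01 / eps
  i <- beer_lambert_intensity(c(0, dd), opt, s)
  expect_equal(log(i[1] / i[2]), eps * dd, tolerance = 1e-12)
  # first-order regime: AC/DC approximates eps*c*delta_d within 1%
  expect_equal((i[1] - i[2]) / i[1], eps * dd, tolerance = 0.01)
  # doubling concentration while halving the modulation leaves AC/DC
  # unchanged within 1%
  opt2 <- optical_params(i0 = 2, eps_hbo2 = 1.1, eps_hb = 0.8, hb_conc = 2,
                         d_static = 0.5)
  i2 <- beer_lambert_intensity(c(0, dd / 2), opt2, s)
  expect_equal((i2[1] - i2[2]) / i2[1], (i[1] - i[2]) / i[1], tolerance = 0.01)
  expect_error(beer_lambert_intensity(c(-1, 0), opt, s), "negative")
})

test_that("venous pooling increment is confined to the occlusion epoch", {
  opt <- optical_params(venous_path = 0.3)
  n <- 3000; fs <- 10
  mask <- rep(FALSE, n); mask[1001:2000] <- TRUE
  i0 <- beer_lambert_intensity(rep(0, n), opt, 0.97)
  iv <- beer_lambert_intensity(rep(0, n), opt, 0.97, occluded_mask = mask,
                               sampling_rate = fs)
  expect_equal(iv[!mask], i0[!mask])
  expect_true(all(iv[mask] <= i0[mask]))
  mid <- 1400:1600  # plateau, past the 10-s ramps
  eps <- 0.97 * opt$eps_hbo2 + 0.03 * opt$eps_hb
  expect_equal(unique(round(iv[mid] / i0[mid], 10)),
               round(exp(-eps * 0.3), 10))
})

test_that("simulated sessions are bit-identical under the same seed", {
  a <- simulate_session(seed = 11)
  b <- simulate_session(seed = 11)
  expect_identical(a$signals, b$signals)
  c <- simulate_session(seed = 12)
  expect_false(identical(a$signals, c$signals))
})

test_that("pure systemic drift produces the same envelope on both channels", {
  rec <- simulate_session(subject_params(hyperemia_gain = 1, drift_gain = 1.2),
                          noise = noise_model(sd = 0, wander_amplitude = 0),
                          seed = 3)
  res <- analyze_recording(rec)
  expect_equal(res$ratio_test, res$ratio_control, tolerance = 0.01)
  expect_equal(res$ratio_control, 1.2, tolerance = 0.02)
})

test_that("recording CSV + JSON sidecar round-trips exactly", {
  rec <- simulate_session(timeline = protocol_timeline(ntg = TRUE), seed = 21)
  csv <- tempfile(fileext = ".csv")
  write_recording(rec, csv)
  back <- read_recording(csv)
  expect_identical(back$signals$test_arm, rec$signals$test_arm)
  expect_identical(back$signals$control_arm, rec$signals$control_arm)
  expect_identical(back$signals$time_s, rec$signals$time_s)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$polarity, rec$polarity)
  expect_equal(unclass(back$timeline), unclass(rec$timeline))
  expect_equal(back$ground_truth$hyperemia_gain,
               rec$ground_truth$hyperemia_gain)
  unlink(c(csv, rhpav:::sidecar_path(csv)))
})
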