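# twitch kinetics: extrema, dissection, frequency, velocity, fatigue

test_that("flat traces yield no extrema and no events", {
  tr <- displacement_trace(seq(0, 1, 0.02), rep(0, 51))
  ex <- detect_extrema(tr)
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)
  expect_equal(nrow(dissect_twitches(tr, ex)), 0)
})

test_that("rectified 5 Hz sine over 2 s yields 10 alternating maxima", {
  g <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1,
                                    duration = 2, sample_interval = 0.02), 1)
  ex <- detect_extrema(g$trace)
  expect_length(ex$maxima, 10)
  # oracle: exhaustive scan of strict local maxima
  x <- g$trace$displacement
  scan <- which(x[2:99] > x[1:98] & x[2:99] > x[3:100]) + 1L
  expect_equal(ex$maxima, scan)
  # strict alternation of the combined sequence
  kinds <- c(rep(1, length(ex$maxima)), rep(-1, length(ex$minima)))
  o <- order(c(ex$maxima, ex$minima))
  expect_true(all(diff(kinds[o]) != 0))
})

test_that("a single triangular pulse gives one bracketed maximum", {
  x <- c(rep(0, 10), seq(0, 1, length.out = 11), seq(0.9, 0, length.out = 10),
         rep(0, 10))
  tr <- displacement_trace(seq_along(x) * 0.02 - 0.02, x)
  ex <- detect_extrema(tr)
  expect_length(ex$maxima, 1)
  ev <- dissect_twitches(tr, ex)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 1)
})

test_that("non-finite samples are rejected", {
  expect_error(detect_extrema(c(0, NA, 1)), "non-finite")
})

test_that("asymmetric twitches dissect into the generator's phase times", {
  g <- generate_trace(waveform_spec("asymmetric_twitch", frequency = 2,
                                    amplitude = 2, acceleration_fraction = 0.3,
                                    duration = 2, sample_interval = 0.02), 1)
  ev <- dissect_twitches(g$trace)
  expect_equal(nrow(ev), nrow(g$truth))
  expect_true(all(abs(ev$acceleration_time - 0.15) <= 0.02 + 1e-9))
  expect_true(all(abs(ev$relaxation_time - 0.35) <= 0.02 + 1e-9))
})

test_that("symmetric sine twitches have equal phase durations within dt", {
  g <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1,
                                    duration = 2, sample_interval = 0.02), 1)
  ev <- dissect_twitches(g$trace)
  expect_true(all(abs(ev$acceleration_time - ev$relaxation_time) <= 0.02 + 1e-9))
})

test_that("a truncated final rise yields no event", {
  # 1.3 periods: last rise has no closing minimum
  t <- seq(0, 0.65, 0.01)
  x <- 0.5 * (1 - cos(2 * pi * 2 * t))
  tr <- displacement_trace(t, x)
  ev <- dissect_twitches(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_index, which.max(x[1:40]))
})

test_that("dominant frequency hits the padded FFT bin for clean and noisy traces", {
  g <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1,
                                    duration = 2, sample_interval = 0.02), 1)
  expect_lt(abs(dominant_frequency(g$trace) - 5), 0.125)
  flat <- displacement_trace(seq(0, 1, 0.02), rep(0, 51))
  expect_equal(dominant_frequency(flat), 0)
  gn <- generate_trace(waveform_spec("asymmetric_twitch", frequency = 2,
                                     amplitude = 1, acceleration_fraction = 0.3,
                                     noise_sd = 0.1, duration = 2,
                                     sample_interval = 0.02), 5)
  expect_lt(abs(dominant_frequency(gn$trace) - 2), 0.125)
})

test_that("contraction velocity reproduces closed forms", {
  flat <- displacement_trace(seq(0, 2.5, 0.02), rep(0, 126))
  expect_equal(contraction_velocity(flat), 0)
  ramp <- displacement_trace(seq(0, 2.5, 0.02), seq(0, 2.5, 0.02))
  expect_equal(contraction_velocity(ramp), 1.0)
  short <- displacement_trace(seq(0, 1, 0.02), seq(0, 1, 0.02))
  expect_error(contraction_velocity(short), "shorter")
})

test_that("velocity through the full PIV chain matches the analytic mean speed", {
  fx <- tracked_sine_movie()
  v <- contraction_velocity(fx$trace, 1.96)
  expect_lt(abs(v - 4 * 2 * 5 / 2) / (4 * 2 * 5 / 2), 0.1)  # 2Af = 20 um/s
})

test_that("fatigue timing matches the analytic envelope crossing", {
  fts <- vapply(1:10, function(s) fatigue_time(fatigue_fixture(s), 2),
                numeric(1))
  expect_lt(abs(mean(fts) - fatigue_analytic()) / fatigue_analytic(), 0.15)
})

test_that("non-decaying and never-moving traces resolve per the cessation rule", {
  g <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1,
                                    noise_sd = 0.05, duration = 15,
                                    sample_interval = 0.02), 3)
  b <- generate_trace(waveform_spec("flat", noise_sd = 0.05, duration = 2,
                                    sample_interval = 0.02), 4)
  tr <- displacement_trace(c(b$trace$times, g$trace$times + 2),
                           c(b$trace$displacement, g$trace$displacement))
  expect_true(is.na(fatigue_time(tr, 2)))
  still <- generate_trace(waveform_spec("flat", noise_sd = 0.05, duration = 10,
                                        sample_interval = 0.02), 5)
  expect_lt(fatigue_time(still$trace, 2), 0.1)
  expect_error(fatigue_time(still$trace, 0), "baseline")
})

test_that("event durations are invariant to time shifts of the trace", {
  g <- generate_trace(waveform_spec("asymmetric_twitch", frequency = 2,
                                    amplitude = 1, acceleration_fraction = 0.3,
                                    duration = 2, sample_interval = 0.02), 2)
  ev1 <- dissect_twitches(g$trace)
  pad <- 25L
  x2 <- c(rep(0, pad), g$trace$displacement)
  tr2 <- displacement_trace((seq_along(x2) - 1) * 0.02, x2)
  ev2 <- dissect_twitches(tr2)
  expect_equal(ev2$peak_index, ev1$peak_index + pad)
  expect_equal(ev2$acceleration_time, ev1$acceleration_time)
  expect_equal(ev2$amplitude, ev1$amplitude)
})

test_that("amplitudes scale with the trace, times do not", {
  g <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1,
                                    noise_sd = 0.03, duration = 2,
                                    sample_interval = 0.02), 8)
  ev1 <- dissect_twitches(g$trace)
  tr2 <- displacement_trace(g$trace$times, g$trace$displacement * 3)
  ev2 <- dissect_twitches(tr2)
  expect_equal(ev2$amplitude, 3 * ev1$amplitude)
  expect_equal(ev2$peak_index, ev1$peak_index)
  expect_equal(ev2$relaxation_time, ev1$relaxation_time)
})

test_that("phase times and frequency are recovered across seeded noisy traces", {
  acc_err <- c(); rel_err <- c()
  for (s in 1:100) {
    g <- generate_trace(waveform_spec("asymmetric_twitch", frequency = 5,
                                      amplitude = 1,
                                      acceleration_fraction = 0.3,
                                      noise_sd = 0.1, duration = 2,
                                      sample_interval = 0.02), s)
    ev <- dissect_twitches(g$trace)
    expect_lt(abs(dominant_frequency(g$trace) - 5), 0.125 + 1e-9)
    # match detected events to the planted twitches by peak time
    for (j in seq_len(nrow(g$truth))) {
      k <- which.min(abs(ev$peak_time - g$truth$peak_time[j]))
      if (!length(k) || abs(ev$peak_time[k] - g$truth$peak_time[j]) > 0.1)
        next
      acc_err <- c(acc_err, abs(ev$acceleration_time[k] - 0.06))
      rel_err <- c(rel_err, abs(ev$relaxation_time[k] - 0.14))
    }
  }
  expect_gt(length(acc_err), 500)
  expect_lte(median(acc_err), 0.02 + 1e-9)
  expect_lte(median(rel_err), 0.02 + 1e-9)
})

test_that("kinetics summary combines the per-trace measures coherently", {
  g <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1,
                                    duration = 2, sample_interval = 0.02), 1)
  s <- summarize_kinetics(g$trace)
  expect_equal(s$dominant_frequency, 5, tolerance = 0.125)
  expect_equal(s$period, 1 / s$dominant_frequency)
  # 9 complete cycles close within the sampled range; the final relaxation
  # runs past the last sample and is not scored as an event
  expect_equal(s$n_twitches, 9)
})
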