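# synthetic-data generators: traces, movies, morphology scenes, Ct tables

test_that("flat and zero-amplitude traces are exactly zero with empty truth", {
  g <- generate_trace(waveform_spec("flat", duration = 2,
                                    sample_interval = 0.02), 1)
  expect_length(g$trace$displacement, 100)
  expect_true(all(g$trace$displacement == 0))
  expect_equal(nrow(g$truth), 0)
})

test_that("sine trace matches its closed form and period", {
  sp <- waveform_spec("sine", frequency = 5, amplitude = 1, duration = 2,
                      sample_interval = 0.02)
  g <- generate_trace(sp, 1)
  t <- g$trace$times
  expect_equal(g$trace$displacement, 0.5 * (1 - cos(2 * pi * 5 * t)))
  expect_equal(max(g$trace$displacement), 1)
  expect_true(all(abs(diff(g$truth$peak_time) - 0.2) < 1e-12))
  expect_equal(g$truth$acceleration_time, rep(0.1, nrow(g$truth)))
})

test_that("asymmetric twitch ground truth encodes the rise fraction", {
  g <- generate_trace(waveform_spec("asymmetric_twitch", frequency = 2,
                                    amplitude = 1, acceleration_fraction = 0.3,
                                    duration = 2, sample_interval = 0.02), 1)
  expect_equal(g$truth$acceleration_time, rep(0.15, nrow(g$truth)))
  expect_equal(g$truth$relaxation_time, rep(0.35, nrow(g$truth)))
  # waveform is continuous and spans [0, amplitude]
  expect_gte(min(g$trace$displacement), 0)
  expect_equal(max(g$trace$displacement), max(g$truth$amplitude),
               tolerance = 0.01)
})

test_that("fatigue envelope multiplies amplitudes by exp(-t/decay_time)", {
  g <- generate_trace(waveform_spec("fatigue_decay", frequency = 5,
                                    amplitude = 2, decay_time = 3,
                                    duration = 4, sample_interval = 0.02), 1)
  expect_equal(g$truth$amplitude, 2 * exp(-g$truth$peak_time / 3))
})

test_that("waveform_spec rejects invalid parameters by name", {
  expect_error(waveform_spec("sine", frequency = 30, sample_interval = 0.02),
               "Nyquist")
  expect_error(waveform_spec("sine", amplitude = -1), "amplitude")
  expect_error(waveform_spec("asymmetric_twitch", acceleration_fraction = 1),
               "acceleration_fraction")
})

test_that("generators are deterministic under a fixed seed", {
  sp <- waveform_spec("sine", frequency = 5, amplitude = 1, noise_sd = 0.1,
                      duration = 1, sample_interval = 0.02)
  expect_identical(generate_trace(sp, 42), generate_trace(sp, 42))
  scn <- morphology_scene()
  expect_identical(generate_morphology_image(scn, 7),
                   generate_morphology_image(scn, 7))
  mv1 <- generate_movie(sp, contractility_scene(), 5)
  mv2 <- generate_movie(sp, contractility_scene(), 5)
  expect_identical(mv1$movie$frames[[3]], mv2$movie$frames[[3]])
})

test_that("zero-amplitude movies have identical frames and zero truth", {
  mv <- generate_movie(waveform_spec("flat", duration = 0.1,
                                     sample_interval = 0.02),
                       contractility_scene(), 1)
  expect_equal(mv$movie$frames[[1]], mv$movie$frames[[5]])
  expect_true(all(mv$truth$displacement_um == 0))
})

test_that("movie displacement converts micrometres to pixels as rendered", {
  # A = 2 um at 0.5 um/px -> peak ground-truth displacement 4 px
  mv <- generate_movie(waveform_spec("sine", frequency = 5, amplitude = 2,
                                     duration = 0.4, sample_interval = 0.02),
                       contractility_scene(), 1)
  expect_equal(max(mv$truth$displacement_um) / mv$movie$pixel_size, 4,
               tolerance = 1e-9)
  # and a rendered frame equals the base Fourier-shifted by that amount
  k <- which.max(mv$truth$displacement_um)
  shifted <- twitchkit:::.fourier_shift(mv$movie$frames[[1]],
                                        mv$truth$displacement_um[k] / 0.5, 0)
  expect_lt(max(abs(shifted - mv$movie$frames[[k]])), 1e-8)
})

test_that("displacement exceeding the image margin is rejected", {
  expect_error(
    generate_movie(waveform_spec("sine", frequency = 5, amplitude = 20,
                                 duration = 0.4, sample_interval = 0.02),
                   contractility_scene(), 1),
    "margin")
})

test_that("rendered nuclei are recoverable at their planted positions", {
  scn <- contractility_scene()
  mv <- generate_movie(waveform_spec("flat", duration = 0.1,
                                     sample_interval = 0.02), scn, 1)
  fr <- mv$movie$frames[[1]]
  # nuclei render as smooth bright domes: segmenting the top of the dome
  # gives a compact disk whose centroid is the planted center
  sm <- twitchkit:::.gauss_blur(fr, 1)
  thr <- stats::median(sm) + 0.7 * (max(sm) - stats::median(sm))
  idx <- which(sm > thr, arr.ind = TRUE)
  cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
  # pixel centers sit at (index - 0.5) * pixel_size in micrometres
  expect_lt(abs(cx - (scn$nuclei$x[1] / 0.5 + 0.5)), 0.5)
  expect_lt(abs(cy - (scn$nuclei$y[1] / 0.5 + 0.5)), 0.5)
})

test_that("morphology ground truth records spacing, BTX class and puncta", {
  scn <- morphology_scene(noise_sd = 0)
  gm <- generate_morphology_image(scn, 1)
  # gaps 50, 50, 50, 25 um along a straight tube
  expect_equal(gm$truth$spacing$mean_gap_um, 43.75)
  expect_equal(gm$truth$high_btx_proportion, 2 / 8)
  expect_equal(nrow(gm$truth$puncta), 25)
  # equally spaced nuclei give CoV 0
  scn2 <- scene_spec(image_size = c(120L, 500L), pixel_size = 0.5,
                     tubes = list(list(centerline = cbind(c(15, 235), c(30, 30)),
                                       width = 20)),
                     nuclei = data.frame(x = seq(25, 225, by = 50), y = 30,
                                         radius = 3, tube = 1L))
  gm2 <- generate_morphology_image(scn2, 1)
  expect_equal(gm2$truth$spacing$cov, 0)
  expect_equal(gm2$truth$spacing$mean_gap_um, 50)
})

test_that("overlapping same-tube nuclei are rejected", {
  scn <- scene_spec(image_size = c(120L, 300L), pixel_size = 0.5,
                    tubes = list(list(centerline = cbind(c(15, 135), c(30, 30)),
                                      width = 20)),
                    nuclei = data.frame(x = c(50, 53), y = 30, radius = 3,
                                        tube = 1L))
  expect_error(generate_morphology_image(scn, 1), "separation")
})

test_that("Ct tables encode the requested fold changes exactly at zero noise", {
  ct <- generate_ct_table(c("a", "b", "c"), c(0, 1, -0.5))
  res <- ddct(ct)
  expect_equal(res$fold_change, c(1, 2, 2^-0.5))
  expect_equal(res$log2_fc, c(0, 1, -0.5))
  # housekeeping present for every sample
  expect_setequal(unique(ct$sample), ct$sample[ct$gene == "HPRT"])
})
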