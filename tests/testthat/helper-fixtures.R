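# shared fixtures, all generated in code

# standard contractility scene: one horizontal tube with a mid-tube nucleus
# in a 128 x 192 px frame at 0.5 um/px
contractility_scene <- function() {
  scene_spec(image_size = c(128L, 192L), pixel_size = 0.5,
             tubes = list(list(centerline = cbind(c(16, 80), c(32, 32)),
                               width = 20)),
             nuclei = data.frame(x = 48, y = 32, radius = 4, tube = 1L))
}

# standard morphology scene: tube + in-tube and extra-tube nuclei + puncta
morphology_scene <- function(noise_sd = 2) {
  scene_spec(
    image_size = c(200L, 500L), pixel_size = 0.5,
    tubes = list(list(centerline = cbind(c(15, 235), c(50, 50)), width = 20)),
    nuclei = data.frame(
      x = c(50, 100, 150, 200, 225, 30, 90, 150),
      y = c(rep(50, 5), rep(15, 3)),
      radius = 3,
      tube = c(rep(1L, 5), rep(NA, 3)),
      btx_high = c(TRUE, TRUE, FALSE, FALSE, FALSE, rep(FALSE, 3))),
    puncta = data.frame(x = seq(60, 140, length.out = 25), y = rep(54, 25),
                        radius = 0.6),
    noise_sd = noise_sd)
}

# full-frame band-limited speckle for PIV shift tests
piv_texture <- function(nr = 192, nc = 192, seed = 7) {
  twitchkit:::.bandlimit(twitchkit:::.speckle(nr, nc, 3, seed) * 50 + 100)
}

shift_frame <- function(img, dx, dy = 0) twitchkit:::.fourier_shift(img, dx, dy)

interior <- function(m) m[2:(nrow(m) - 1), 2:(ncol(m) - 1), drop = FALSE]

# fatigue trace: flat noisy baseline followed by a decaying waveform
fatigue_fixture <- function(seed, noise_sd = 0.05, amplitude = 1,
                            frequency = 5, decay_time = 4,
                            baseline = 2, duration = 15, dt = 0.02) {
  g <- generate_trace(waveform_spec("fatigue_decay", frequency = frequency,
                                    amplitude = amplitude,
                                    decay_time = decay_time,
                                    noise_sd = noise_sd, duration = duration,
                                    sample_interval = dt), seed)
  b <- generate_trace(waveform_spec("flat", noise_sd = noise_sd,
                                    duration = baseline,
                                    sample_interval = dt), seed + 10000L)
  displacement_trace(c(b$trace$times, g$trace$times + baseline),
                     c(b$trace$displacement, g$trace$displacement))
}

# analytic fatigue crossing time for fatigue_fixture parameters: the rolling
# RMS velocity sqrt(sig^2 + noise^2) crosses factor * baseline RMS when the
# signal RMS A*pi*f*exp(-t/tau)/sqrt(2) falls to sqrt(factor^2 - 1) * noise
fatigue_analytic <- function(noise_sd = 0.05, amplitude = 1, frequency = 5,
                             decay_time = 4, dt = 0.02, factor = 2) {
  v_noise <- sqrt(2) * noise_sd / dt
  sig0 <- amplitude * pi * frequency / sqrt(2)
  decay_time * log(sig0 / (sqrt(factor^2 - 1) * v_noise))
}

# cache expensive PIV products across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tracked_sine_movie <- function() {
  cached("sine_movie", {
    mv <- generate_movie(waveform_spec("sine", frequency = 5, amplitude = 2,
                                       duration = 2, sample_interval = 0.02),
                         contractility_scene(), seed = 3)
    fields <- movie_to_fields(mv$movie)
    trace <- track_point(fields, c(96, 64), 0.5, 0.02)
    list(mv = mv, fields = fields, trace = trace)
  })
}

# digital disk mask
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix((g$x - cx)^2 + (g$y - cy)^2 <= r^2, n, n)
}
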