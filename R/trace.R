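#' Displacement trace of a tracked reference point
#'
#' A `displacement_trace` holds the distance of a tracked point (typically a
#' myonucleus) from its initial position over time, plus per-interval
#' instantaneous speeds. It is the common currency between the PIV tracker,
#' the synthetic generator and the kinetics layer.
#'
#' @param times sample times in seconds (uniformly spaced).
#' @param displacement distance from the initial position, in micrometres;
#'   the first sample must be 0.
#' @param velocity per-interval instantaneous speed in um/s (length
#'   `length(times) - 1`); computed from `displacement` when omitted.
#' @param source label of the tracked reference point.
#' @param truncated logical; `TRUE` when tracking left the vector-field hull
#'   and the trace was cut short.
#' @return an object of class `displacement_trace`.
#' @export
displacement_trace <- function(times, displacement, velocity = NULL,
                               source = "point", truncated = FALSE) {
  if (length(times) != length(displacement))
    .stop_invalid("trace", "times and displacement lengths differ")
  if (length(times) < 2L)
    .stop_invalid("trace", "need at least 2 samples")
  if (abs(displacement[1]) > 1e-9)
    .stop_invalid("trace", "displacement must start at 0")
  dt <- diff(times)
  if (any(dt <= 0)) .stop_invalid("trace", "times must be strictly increasing")
  if (is.null(velocity)) velocity <- abs(diff(displacement)) / dt
  if (length(velocity) != length(times) - 1L)
    .stop_invalid("trace", "velocity must have length(times) - 1 entries")
  structure(list(times = as.numeric(times),
                 displacement = as.numeric(displacement),
                 velocity = as.numeric(velocity),
                 source = source, truncated = isTRUE(truncated)),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("displacement_trace '%s': %d samples over %.3f s, peak %.3f um%s\n",
              x$source, length(x$times), diff(range(x$times)),
              max(x$displacement), if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

.trace_dt <- function(trace) {
  dt <- diff(trace$times)
  if (diff(range(dt)) > 1e-9 * max(dt))
    stop("trace is not uniformly sampled", call. = FALSE)
  dt[1]
}

#' Specify a displacement waveform for the synthetic generator
#'
#' Describes the motion regime a synthetic myotube is paced with. `sine`
#' produces a rectified sinusoid rising from 0 to `amplitude`;
#' `asymmetric_twitch` rises for `acceleration_fraction` of each period and
#' relaxes for the remainder (smooth raised-cosine segments);
#' `fatigue_decay` is the sine waveform under an exponential envelope
#' `exp(-t / decay_time)`; `flat` is zero signal. Gaussian noise of
#' `noise_sd` um is added on top of every waveform.
#'
#' @param kind one of `"sine"`, `"asymmetric_twitch"`, `"flat"`,
#'   `"fatigue_decay"`.
#' @param frequency pacing frequency in Hz (ignored for `flat`).
#' @param amplitude peak displacement in micrometres.
#' @param acceleration_fraction fraction of each period spent rising,
#'   strictly in (0, 1).
#' @param decay_time fatigue envelope e-folding time in seconds (`Inf` for a
#'   non-fatiguing waveform).
#' @param noise_sd additive Gaussian noise, micrometres.
#' @param duration trace duration, seconds.
#' @param sample_interval sampling interval, seconds. `frequency *
#'   sample_interval` must stay below 0.5 (Nyquist).
#' @return a validated `waveform_spec` object.
#' @export
waveform_spec <- function(kind = c("sine", "asymmetric_twitch", "flat",
                                   "fatigue_decay"),
                          frequency = 1, amplitude = 1,
                          acceleration_fraction = 0.5, decay_time = Inf,
                          noise_sd = 0, duration = 2, sample_interval = 0.02) {
  kind <- match.arg(kind)
  if (!is.finite(amplitude) || amplitude < 0)
    .stop_invalid("waveform_spec", "amplitude must be >= 0")
  if (kind != "flat") {
    if (!is.finite(frequency) || frequency <= 0)
      .stop_invalid("waveform_spec", "frequency must be > 0")
    if (frequency * sample_interval >= 0.5)
      .stop_invalid("waveform_spec",
                    "frequency * sample_interval must be < 0.5 (Nyquist)")
  }
  if (!(acceleration_fraction > 0 && acceleration_fraction < 1))
    .stop_invalid("waveform_spec", "acceleration_fraction must be in (0, 1)")
  if (!(decay_time > 0)) .stop_invalid("waveform_spec", "decay_time must be > 0")
  if (noise_sd < 0) .stop_invalid("waveform_spec", "noise_sd must be >= 0")
  if (duration <= 0 || sample_interval <= 0)
    .stop_invalid("waveform_spec", "duration and sample_interval must be > 0")
  structure(list(kind = kind, frequency = frequency, amplitude = amplitude,
                 acceleration_fraction = acceleration_fraction,
                 decay_time = decay_time, noise_sd = noise_sd,
                 duration = duration, sample_interval = sample_interval),
            class = "waveform_spec")
}

# noise-free waveform value at times t (vectorized)
.waveform_value <- function(spec, t) {
  A <- spec$amplitude
  f <- spec$frequency
  switch(spec$kind,
    flat = rep(0, length(t)),
    sine = A * 0.5 * (1 - cos(2 * pi * f * t)),
    fatigue_decay = A * 0.5 * (1 - cos(2 * pi * f * t)) * exp(-t / spec$decay_time),
    asymmetric_twitch = {
      Tp <- 1 / f
      aT <- spec$acceleration_fraction * Tp
      tau <- t %% Tp
      ifelse(tau < aT,
             A * 0.5 * (1 - cos(pi * tau / aT)),
             A * 0.5 * (1 + cos(pi * (tau - aT) / (Tp - aT))))
    })
}

# ground-truth twitch table for complete cycles inside [0, t_last]
.waveform_truth <- function(spec, t_last) {
  empty <- data.frame(start_time = numeric(0), peak_time = numeric(0),
                      end_time = numeric(0), amplitude = numeric(0),
                      acceleration_time = numeric(0),
                      relaxation_time = numeric(0))
  if (spec$kind == "flat" || spec$amplitude == 0) return(empty)
  Tp <- 1 / spec$frequency
  accel <- if (spec$kind == "asymmetric_twitch")
    spec$acceleration_fraction * Tp else Tp / 2
  K <- floor(t_last / Tp + 1e-9)
  if (K < 1) return(empty)
  k <- seq_len(K) - 1
  peak <- k * Tp + accel
  amp <- rep(spec$amplitude, K)
  if (spec$kind == "fatigue_decay") amp <- amp * exp(-peak / spec$decay_time)
  data.frame(start_time = k * Tp, peak_time = peak, end_time = (k + 1) * Tp,
             amplitude = amp, acceleration_time = accel,
             relaxation_time = Tp - accel)
}

#' Generate a synthetic displacement trace with ground truth
#'
#' Samples the waveform described by `spec` and returns both the noisy trace
#' and the exact per-twitch ground truth (extrema times, amplitudes,
#' acceleration and relaxation durations) for every complete cycle within
#' the sampled range.
#'
#' @param spec a [waveform_spec()].
#' @param seed integer seed fixing all randomness.
#' @return list with elements `trace` (a [displacement_trace()]) and
#'   `truth` (data frame, one row per complete twitch).
#' @examples
#' tr <- generate_trace(waveform_spec("sine", frequency = 5, amplitude = 1), 1)
#' nrow(tr$truth)
#' @export
generate_trace <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "waveform_spec"))
  n <- round(spec$duration / spec$sample_interval)
  t <- (seq_len(n) - 1) * spec$sample_interval
  x <- .waveform_value(spec, t)
  if (spec$noise_sd > 0)
    x <- x + .with_seed(seed, rnorm(n, 0, spec$noise_sd))
  x[1] <- 0  # trace is displacement from the initial position
  list(trace = displacement_trace(t, x, source = sprintf("synthetic_%s", spec$kind)),
       truth = .waveform_truth(spec, t[n]))
}
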