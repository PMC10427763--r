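#' Detect alternating extrema of a displacement trace
#'
#' Finds local maxima and minima whose prominence is at least
#' `prominence_fraction` of the trace's global range, then enforces strict
#' alternation (of two same-kind neighbors the more extreme survives).
#' Boundary samples are admitted as flanking minima when the trace rises
#' from (or falls to) them by at least the prominence threshold, so that
#' twitches starting or ending at the recording edges stay bracketed.
#'
#' @param trace a [displacement_trace()] or numeric vector.
#' @param prominence_fraction relative prominence threshold (default 0.1).
#' @param smooth_window odd width of the binomial smoother applied before
#'   candidate detection (default 3; 1 disables). Unsampled noise otherwise
#'   splits flat twitch summits into double peaks whose dip prominence can
#'   exceed any reasonable threshold.
#' @return list with integer index vectors `minima` and `maxima`; the
#'   combined sorted sequence alternates strictly.
#' @export
detect_extrema <- function(trace, prominence_fraction = 0.1,
                           smooth_window = 3L) {
  x_raw <- if (inherits(trace, "displacement_trace")) trace$displacement else trace
  if (length(x_raw) < 3L) stop("trace must have at least 3 samples", call. = FALSE)
  if (any(!is.finite(x_raw))) stop("trace contains non-finite samples", call. = FALSE)
  x <- if (smooth_window > 1L) .binomial_smooth(x_raw, smooth_window) else x_raw
  rng <- max(x) - min(x)
  empty <- list(minima = integer(0), maxima = integer(0))
  if (rng == 0) return(empty)
  thr <- prominence_fraction * rng
  peaks <- .prominent_extrema(x, thr)          # maxima of x
  troughs <- .prominent_extrema(-x, thr)       # minima of x
  kind <- c(rep(1L, length(peaks)), rep(-1L, length(troughs)))
  idx <- c(peaks, troughs)
  o <- order(idx); idx <- idx[o]; kind <- kind[o]
  # strict alternation: in runs of one kind keep the most extreme
  if (length(idx)) {
    keep <- logical(length(idx))
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      while (j < length(idx) && kind[j + 1L] == kind[i]) j <- j + 1L
      run <- i:j
      best <- run[if (kind[i] == 1L) which.max(x[idx[run]]) else which.min(x[idx[run]])]
      keep[best] <- TRUE
      i <- j + 1L
    }
    idx <- idx[keep]; kind <- kind[keep]
  }
  # flanking boundary minima bracketing the first/last maximum, located on
  # the raw series; across a flat run the tie closest to the peak marks the
  # true phase boundary
  if (length(idx) && kind[1] == 1L) {
    seg <- 1:idx[1]
    mval <- min(x_raw[seg])
    m <- seg[max(which(x_raw[seg] == mval))]
    if (x_raw[idx[1]] - mval >= thr && m < idx[1]) {
      idx <- c(m, idx); kind <- c(-1L, kind)
    }
  }
  n <- length(idx)
  if (n && kind[n] == 1L) {
    seg <- idx[n]:length(x_raw)
    mval <- min(x_raw[seg])
    m <- seg[min(which(x_raw[seg] == mval))]
    # the final sample never closes a twitch: the relaxation may continue
    # beyond the recording, which would bias the measured duration short
    if (x_raw[idx[n]] - mval >= thr && m > idx[n] && m < length(x_raw)) {
      idx <- c(idx, m); kind <- c(kind, -1L)
    }
  }
  # smoothing can drag an extremum a sample toward the flatter side; snap
  # each index back to the raw-series extremum within the smoothing window
  if (smooth_window > 1L && length(idx)) {
    h <- smooth_window %/% 2L
    for (q in seq_along(idx)) {
      lo <- max(1L, idx[q] - h); hi <- min(length(x_raw), idx[q] + h)
      if (q > 1L) lo <- max(lo, idx[q - 1L] + 1L)
      if (q < length(idx)) hi <- min(hi, idx[q + 1L] - 1L)
      if (lo > hi) next
      seg <- lo:hi
      v <- if (kind[q] == 1L) x_raw[seg] else -x_raw[seg]
      best <- seg[v == max(v)]
      idx[q] <- best[which.min(abs(best - idx[q]))]  # nearest tie is stable
    }
  }
  list(minima = idx[kind == -1L], maxima = idx[kind == 1L])
}

# centered binomial smoother (edges: shrinking symmetric windows)
.binomial_smooth <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  w <- choose(width - 1L, 0:(width - 1L))
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    ww <- choose(2L * k, 0:(2L * k))
    out[i] <- sum(x[(i - k):(i + k)] * ww) / sum(ww)
  }
  out
}

# interior local maxima of x with prominence >= thr (plateaus -> middle index)
.prominent_extrema <- function(x, thr) {
  n <- length(x)
  # run-length encode to handle plateaus
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  m <- length(vals)
  if (m < 3L) return(integer(0))
  cand <- which(vals[2:(m - 1L)] > vals[1:(m - 2L)] &
                vals[2:(m - 1L)] > vals[3:m]) + 1L
  if (!length(cand)) return(integer(0))
  out <- integer(0)
  for (ci in cand) {
    pv <- vals[ci]
    # walk left/right to the nearest strictly higher value; the col on each
    # side is the minimum in between (boundary counts as a col)
    lmin <- pv; i <- ci - 1L
    while (i >= 1L && vals[i] <= pv) { lmin <- min(lmin, vals[i]); i <- i - 1L }
    rmin <- pv; i <- ci + 1L
    while (i <= m && vals[i] <= pv) { rmin <- min(rmin, vals[i]); i <- i + 1L }
    if (pv - max(lmin, rmin) >= thr)
      out <- c(out, starts[ci] + (r$lengths[ci] - 1L) %/% 2L)
  }
  out
}

#' Dissect a trace into twitch events
#'
#' Emits one event per minimum-maximum-minimum triple of the detected
#' extrema: amplitude is the peak minus the preceding minimum, the
#' acceleration time spans start minimum to peak, the relaxation time peak
#' to closing minimum. A final rise without a closing minimum yields no
#' event.
#'
#' @param trace a [displacement_trace()].
#' @param extrema output of [detect_extrema()]; recomputed when omitted.
#' @param prominence_fraction forwarded to [detect_extrema()].
#' @return data frame of twitch events: `start_min_index`, `peak_index`,
#'   `end_min_index`, `peak_time`, `amplitude` (um), `acceleration_time`
#'   and `relaxation_time` (s).
#' @export
dissect_twitches <- function(trace, extrema = NULL, prominence_fraction = 0.1) {
  stopifnot(inherits(trace, "displacement_trace"))
  if (is.null(extrema)) extrema <- detect_extrema(trace, prominence_fraction)
  x <- trace$displacement
  t <- trace$times
  empty <- data.frame(start_min_index = integer(0), peak_index = integer(0),
                      end_min_index = integer(0), peak_time = numeric(0),
                      amplitude = numeric(0), acceleration_time = numeric(0),
                      relaxation_time = numeric(0))
  if (!length(extrema$maxima)) return(empty)
  rows <- lapply(extrema$maxima, function(p) {
    lo <- extrema$minima[extrema$minima < p]
    hi <- extrema$minima[extrema$minima > p]
    if (!length(lo) || !length(hi)) return(NULL)
    s <- max(lo); e <- min(hi)
    data.frame(start_min_index = s, peak_index = p, end_min_index = e,
               peak_time = t[p], amplitude = x[p] - x[s],
               acceleration_time = t[p] - t[s], relaxation_time = t[e] - t[p])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Dominant contraction frequency by FFT
#'
#' Frequency of the largest non-DC amplitude of the FFT of the
#' mean-subtracted, 4x zero-padded trace. Returns 0 when no spectral bin
#' exceeds `noise_floor_factor` times the median spectral amplitude (flat
#' or noise-only traces).
#'
#' @param trace a [displacement_trace()] (>= 8 uniformly spaced samples).
#' @param pad_factor zero-padding multiple of the trace length.
#' @param noise_floor_factor multiple of the median spectral amplitude a
#'   peak must exceed to count.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(trace, pad_factor = 4L, noise_floor_factor = 5) {
  stopifnot(inherits(trace, "displacement_trace"))
  x <- trace$displacement
  if (length(x) < 8L) stop("need at least 8 samples", call. = FALSE)
  dt <- .trace_dt(trace)
  n <- length(x)
  nfft <- pad_factor * n
  sp <- Mod(fft(c(x - mean(x), rep(0, nfft - n))))[2:(nfft %/% 2 + 1L)]
  freqs <- seq_len(nfft %/% 2) / (nfft * dt)
  floor_amp <- noise_floor_factor * median(sp)
  if (max(sp) <= floor_amp || max(sp) == 0) return(0)
  freqs[which.max(sp)]
}

#' Mean contraction velocity over an analysis window
#'
#' Mean of the per-interval instantaneous speeds over the first `window`
#' seconds of the trace.
#'
#' @param trace a [displacement_trace()] spanning at least `window` seconds.
#' @param window analysis window, seconds (default 2).
#' @return mean speed in um/s.
#' @export
contraction_velocity <- function(trace, window = 2.0) {
  stopifnot(inherits(trace, "displacement_trace"))
  t0 <- trace$times[1]
  if (diff(range(trace$times)) < window - 1e-9)
    stop(sprintf(paste0("trace spans %.3f s, shorter than the %.3f s window; ",
                        "pass an explicit shorter `window`"),
                 diff(range(trace$times)), window), call. = FALSE)
  # velocity[k] covers the interval (t[k], t[k+1])
  sel <- trace$times[-1] <= t0 + window + 1e-9
  mean(abs(trace$velocity[sel]))
}

#' Time to fatigue under sustained stimulation
#'
#' The trace's first `baseline_window` seconds are an unstimulated baseline
#' used to estimate the resting RMS velocity. Fatigue time is the first
#' instant after stimulation onset (the end of the baseline) from which the
#' rolling RMS velocity stays below `stop_threshold_factor` times the
#' baseline RMS for at least `sustain` seconds, measured from onset. `NA`
#' when motion never ceases by that criterion.
#'
#' @param trace a [displacement_trace()] beginning with the baseline.
#' @param baseline_window baseline duration, seconds.
#' @param stop_threshold_factor cessation threshold as a multiple of the
#'   baseline RMS velocity (default 2).
#' @param sustain required sub-threshold duration, seconds (default 1).
#' @param rms_window rolling RMS window, seconds (default 1; shorter
#'   windows make the estimate spiky and bias the detected time late).
#' @return fatigue time in seconds, or `NA` if never reached.
#' @export
fatigue_time <- function(trace, baseline_window, stop_threshold_factor = 2.0,
                         sustain = 1.0, rms_window = 1.0) {
  stopifnot(inherits(trace, "displacement_trace"))
  dt <- .trace_dt(trace)
  tv <- (trace$times[-1] + trace$times[-length(trace$times)]) / 2
  v2 <- trace$velocity^2
  base <- tv < baseline_window
  if (sum(base) < 2L)
    stop("trace lacks a pre-stimulation baseline of the requested length",
         call. = FALSE)
  base_rms <- sqrt(mean(v2[base]))
  k <- max(1L, round(rms_window / dt))
  roll <- sqrt(zoo::rollapply(v2, k, mean, partial = TRUE, align = "center"))
  thr <- stop_threshold_factor * base_rms
  post <- which(tv >= baseline_window)
  below <- roll[post] < thr
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  need <- max(1L, ceiling(sustain / dt))
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  max(tv[post[starts[hit[1]]]] - baseline_window, 0)
}

#' Summarize twitch kinetics of one trace
#'
#' One-row summary combining [contraction_velocity()],
#' [dominant_frequency()] (with the implied period), mean acceleration and
#' relaxation times over detected twitches, twitch count, and optionally
#' [fatigue_time()].
#'
#' @param trace a [displacement_trace()].
#' @param window velocity analysis window, seconds; capped at the trace
#'   span.
#' @param prominence_fraction extrema prominence threshold.
#' @param baseline_window when non-`NULL`, the trace starts with this many
#'   seconds of unstimulated baseline and a fatigue time is reported.
#' @return one-row data frame (a `kinetics_summary`).
#' @export
summarize_kinetics <- function(trace, window = 2.0, prominence_fraction = 0.1,
                               baseline_window = NULL) {
  stopifnot(inherits(trace, "displacement_trace"))
  span <- diff(range(trace$times))
  events <- dissect_twitches(trace, prominence_fraction = prominence_fraction)
  f <- dominant_frequency(trace)
  data.frame(
    contraction_velocity = contraction_velocity(trace, min(window, span)),
    dominant_frequency = f,
    period = if (f > 0) 1 / f else NA_real_,
    mean_acceleration_time = if (nrow(events)) mean(events$acceleration_time) else NA_real_,
    mean_relaxation_time = if (nrow(events)) mean(events$relaxation_time) else NA_real_,
    n_twitches = nrow(events),
    fatigue_time = if (is.null(baseline_window)) NA_real_ else
      fatigue_time(trace, baseline_window))
}
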