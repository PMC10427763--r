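#' PIV configuration
#'
#' Parameters for the multipass FFT cross-correlation engine. Defaults
#' follow standard two-pass practice for myotube recordings: 64 px
#' interrogation windows in the first pass, 32 px in the second, 50%
#' overlap, 3-point Gaussian subpixel peak fit, and a normalized-median
#' vector validation test.
#'
#' @param pass_windows decreasing vector of interrogation window sizes in
#'   px; each must be a power of two.
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param subpixel subpixel peak estimator; `"gauss3"` (3-point Gaussian,
#'   with parabolic fallback when a stencil value is not positive).
#' @param validation_threshold normalized median test threshold.
#' @param validation_eps normalization floor of the median test, px.
#' @param max_displacement largest displacement searched per pass, px;
#'   default is a quarter of the pass window.
#' @param highpass_sigma Gaussian sigma (px) of the image high-pass applied
#'   before correlation; structures much larger than the speckle (nuclei,
#'   ribbon shading) otherwise broaden the correlation peak and degrade the
#'   subpixel fit. 0 disables.
#' @return a `piv_config` object.
#' @export
piv_config <- function(pass_windows = c(64L, 32L), overlap_fraction = 0.5,
                       subpixel = "gauss3", validation_threshold = 2.0,
                       validation_eps = 0.1, max_displacement = NULL,
                       highpass_sigma = 4) {
  pass_windows <- as.integer(pass_windows)
  if (any(diff(pass_windows) >= 0))
    .stop_invalid("piv_config", "pass_windows must be strictly decreasing")
  if (any(bitwAnd(pass_windows, pass_windows - 1L) != 0L) || any(pass_windows < 8L))
    .stop_invalid("piv_config", "pass_windows must be powers of two >= 8")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    .stop_invalid("piv_config", "overlap_fraction must be in [0, 1)")
  subpixel <- match.arg(subpixel, "gauss3")
  structure(list(pass_windows = pass_windows,
                 overlap_fraction = overlap_fraction, subpixel = subpixel,
                 validation_threshold = validation_threshold,
                 validation_eps = validation_eps,
                 max_displacement = max_displacement,
                 highpass_sigma = highpass_sigma),
            class = "piv_config")
}

# correlation peak of one mean-subtracted window pair.
# Zero-padded FFT cross-correlation normalized by the window-overlap count
# (the "unbiased" estimator): without the normalization the triangular
# overlap taper skews the peak toward zero in proportion to the shift.
# Returns c(u, v, ok): displacement of B relative to A in px.
.xcorr_peak <- function(A, B, max_disp, subpixel = "gauss3", sd_floor = 0) {
  W <- nrow(A)
  if (sd(A) <= sd_floor || sd(B) <= sd_floor)
    return(c(0, 0, 0))  # no correlation energy (flat or texture-free window)
  A <- A - mean(A); B <- B - mean(B)
  P <- W + 2L * as.integer(ceiling(min(max_disp, W / 2)))
  Ap <- matrix(0, P, P); Ap[seq_len(W), seq_len(W)] <- A
  Bp <- matrix(0, P, P); Bp[seq_len(W), seq_len(W)] <- B
  cc <- Re(fft(Conj(fft(Ap)) * fft(Bp), inverse = TRUE)) / (P * P)
  sh <- c(0:(P / 2), -(P / 2 - 1):-1)[seq_len(P)]    # shift per index
  ov <- pmax(W - abs(sh), 1)                         # overlap rows/cols
  cc <- cc / outer(ov, ov)
  keep <- abs(sh) <= min(max_disp, W - 2)
  cc_m <- cc
  cc_m[!keep, ] <- -Inf
  cc_m[, !keep] <- -Inf
  pk <- arrayInd(which.max(cc_m), dim(cc_m))
  iy <- pk[1]; ix <- pk[2]
  wrap <- function(i) ((i - 1L) %% P) + 1L
  fit1 <- function(cl, c0, cr) {
    if (cl > 0 && c0 > 0 && cr > 0) {
      den <- log(cl) + log(cr) - 2 * log(c0)
      if (den < 0) return(0.5 * (log(cl) - log(cr)) / den)
    }
    den <- cl + cr - 2 * c0
    if (den < 0) 0.5 * (cl - cr) / den else 0
  }
  du <- fit1(cc[iy, wrap(ix - 1L)], cc[iy, ix], cc[iy, wrap(ix + 1L)])
  dv <- fit1(cc[wrap(iy - 1L), ix], cc[iy, ix], cc[wrap(iy + 1L), ix])
  c(sh[ix] + du, sh[iy] + dv, 1)
}

# normalized median test (per component, 8-neighborhood) + replacement
.validate_field <- function(u, v, valid, eps = 0.1, thr = 2.0) {
  ny <- nrow(u); nx <- ncol(u)
  nbrs <- function(M, i, j, ok) {
    ii <- max(1, i - 1):min(ny, i + 1); jj <- max(1, j - 1):min(nx, j + 1)
    sel <- ok[ii, jj, drop = FALSE]
    sel[ii == i, jj == j] <- FALSE
    M[ii, jj, drop = FALSE][sel]
  }
  flag <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!valid[i, j]) next
    nu <- nbrs(u, i, j, valid); nv <- nbrs(v, i, j, valid)
    if (length(nu) < 3L) next
    ru <- abs(u[i, j] - median(nu)) / (median(abs(nu - median(nu))) + eps)
    rv <- abs(v[i, j] - median(nv)) / (median(abs(nv - median(nv))) + eps)
    if (sqrt(ru^2 + rv^2) > thr) flag[i, j] <- TRUE
  }
  ok <- valid & !flag
  replaced <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (ok[i, j]) next
    nu <- nbrs(u, i, j, ok); nv <- nbrs(v, i, j, ok)
    if (length(nu) >= 1L) { u[i, j] <- mean(nu); v[i, j] <- mean(nv) }
    else if (any(ok)) { u[i, j] <- median(u[ok]); v[i, j] <- median(v[ok]) }
    else { u[i, j] <- 0; v[i, j] <- 0 }
    replaced[i, j] <- TRUE
  }
  list(u = u, v = v, valid = ok, replaced = replaced)
}

# bilinear interpolation of a field component at points, clamped to the grid
.field_component_at <- function(field, Z, xp, yp, clamp = TRUE) {
  .bilinear(field$x, field$y, Z, xp, yp, clamp = clamp)
}

#' Displacement field between one frame pair
#'
#' Multipass FFT cross-correlation. The first pass correlates mean-
#' subtracted interrogation windows directly (integer peak + 3-point
#' Gaussian subpixel fit); each subsequent pass deforms `frame_b` by the
#' bilinearly interpolated previous-pass field before correlating, and adds
#' the measured residual to the predictor. Vectors failing the normalized
#' median test are replaced by the mean of their valid 8-neighbors and
#' flagged.
#'
#' @param frame_a,frame_b numeric matrices of the same shape, larger than
#'   the first pass window.
#' @param config a [piv_config()].
#' @return a `piv_field`: grid center coordinates `x`, `y` (px), matrices
#'   `u`, `v`, `magnitude` (px/frame), logical `valid` and `replaced`.
#' @export
correlate_pair <- function(frame_a, frame_b, config = piv_config()) {
  stopifnot(is.matrix(frame_a), is.matrix(frame_b))
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames must share one shape", call. = FALSE)
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  if (min(nr, nc) < config$pass_windows[1])
    stop(sprintf("frame (%d x %d) smaller than the %d px first-pass window",
                 nr, nc, config$pass_windows[1]), call. = FALSE)
  if (!is.null(config$highpass_sigma) && config$highpass_sigma > 0) {
    frame_a <- frame_a - .gauss_blur(frame_a, config$highpass_sigma)
    frame_b <- frame_b - .gauss_blur(frame_b, config$highpass_sigma)
  }
  prev <- NULL
  for (W in config$pass_windows) {
    step <- max(1L, as.integer(round(W * (1 - config$overlap_fraction))))
    x0 <- seq(1L, nc - W + 1L, by = step)
    y0 <- seq(1L, nr - W + 1L, by = step)
    cx <- x0 + (W - 1) / 2
    cy <- y0 + (W - 1) / 2
    nx <- length(x0); ny <- length(y0)
    max_disp <- if (is.null(config$max_displacement)) W / 4 else config$max_displacement
    if (is.null(prev)) {
      bb <- frame_b
      pu <- matrix(0, ny, nx); pv <- matrix(0, ny, nx)
    } else {
      # dense predictor over the full image, clamped beyond the grid hull
      gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      gy <- matrix(seq_len(nr), nr, nc)
      U <- matrix(.field_component_at(prev, prev$u, as.vector(gx), as.vector(gy)), nr, nc)
      V <- matrix(.field_component_at(prev, prev$v, as.vector(gx), as.vector(gy)), nr, nc)
      bb <- matrix(.sample_image(frame_b, as.vector(gx + U), as.vector(gy + V),
                                 fill = mean(frame_b)), nr, nc)
      pu <- matrix(.field_component_at(prev, prev$u, rep(cx, each = ny), rep(cy, nx)), ny, nx)
      pv <- matrix(.field_component_at(prev, prev$v, rep(cx, each = ny), rep(cy, nx)), ny, nx)
    }
    u <- matrix(0, ny, nx); v <- matrix(0, ny, nx)
    valid <- matrix(TRUE, ny, nx)
    sd_floor <- 1e-6 * sd(frame_a)
    for (j in seq_len(nx)) for (i in seq_len(ny)) {
      rows <- y0[i]:(y0[i] + W - 1L); cols <- x0[j]:(x0[j] + W - 1L)
      res <- .xcorr_peak(frame_a[rows, cols], bb[rows, cols], max_disp,
                         config$subpixel, sd_floor)
      u[i, j] <- pu[i, j] + res[1]
      v[i, j] <- pv[i, j] + res[2]
      valid[i, j] <- res[3] == 1
    }
    vf <- .validate_field(u, v, valid, config$validation_eps,
                          config$validation_threshold)
    prev <- structure(list(x = cx, y = cy, u = vf$u, v = vf$v,
                           magnitude = sqrt(vf$u^2 + vf$v^2),
                           valid = vf$valid, replaced = vf$replaced,
                           window = W, step = step),
                      class = "piv_field")
  }
  prev
}

#' @export
print.piv_field <- function(x, ...) {
  cat(sprintf("piv_field: %d x %d vectors (window %d px), mean |d| = %.3f px, %d invalid\n",
              nrow(x$u), ncol(x$u), x$window, mean(x$magnitude), sum(!x$valid)))
  invisible(x)
}

#' Displacement fields for every consecutive frame pair of a movie
#'
#' @param stack a [movie_stack()].
#' @param config a [piv_config()].
#' @return list of `n_frames - 1` [correlate_pair()] fields.
#' @export
movie_to_fields <- function(stack, config = piv_config()) {
  stopifnot(inherits(stack, "movie_stack"))
  n <- length(stack$frames)
  lapply(seq_len(n - 1L), function(k)
    correlate_pair(stack$frames[[k]], stack$frames[[k + 1L]], config))
}

#' Track a reference point through a field sequence
#'
#' Lagrangian integration of the displacement fields: at each interval the
#' point moves by the bilinearly interpolated `(u, v)` at its current
#' position. Displacement is reported as the distance from the initial
#' position in micrometres; velocity is the per-interval step length in
#' um/s. A trajectory leaving the grid hull truncates the trace and flags
#' it.
#'
#' @param fields list of `piv_field`s (consecutive frame pairs).
#' @param start `c(x, y)` starting position in px, inside the grid hull.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param source label for the resulting trace.
#' @return a [displacement_trace()].
#' @export
track_point <- function(fields, start, pixel_size, frame_interval,
                        source = "nucleus") {
  stopifnot(length(start) == 2L, length(fields) >= 1L)
  f1 <- fields[[1]]
  inside <- function(p)
    p[1] >= f1$x[1] && p[1] <= f1$x[length(f1$x)] &&
    p[2] >= f1$y[1] && p[2] <= f1$y[length(f1$y)]
  if (!inside(start))
    stop("start point lies outside the vector-field grid hull", call. = FALSE)
  n <- length(fields)
  disp <- numeric(n + 1L); vel <- numeric(n)
  p <- as.numeric(start)
  truncated <- FALSE
  k_end <- n
  for (k in seq_len(n)) {
    f <- fields[[k]]
    du <- .field_component_at(f, f$u, p[1], p[2], clamp = FALSE)
    dv <- .field_component_at(f, f$v, p[1], p[2], clamp = FALSE)
    if (is.na(du) || is.na(dv)) { truncated <- TRUE; k_end <- k - 1L; break }
    p <- p + c(du, dv)
    disp[k + 1L] <- sqrt(sum((p - start)^2)) * pixel_size
    vel[k] <- sqrt(du^2 + dv^2) * pixel_size / frame_interval
  }
  keep <- seq_len(k_end + 1L)
  displacement_trace(times = (keep - 1) * frame_interval,
                     displacement = disp[keep], velocity = vel[seq_len(k_end)],
                     source = source, truncated = truncated)
}
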