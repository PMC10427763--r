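#' Calibrated movie stack
#'
#' Container for an ordered grayscale frame sequence with its spatial and
#' temporal calibration. Frames are numeric matrices (rows = y, cols = x).
#'
#' @param frames list of 2D numeric matrices, all the same shape.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval seconds per frame (> 0).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval) {
  if (!is.list(frames) || length(frames) < 2L)
    .stop_invalid("movie_stack", "need at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .stop_invalid("movie_stack", "all frames must share one shape")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    .stop_invalid("movie_stack", "pixel_size must be > 0")
  if (!is.finite(frame_interval) || frame_interval <= 0)
    .stop_invalid("movie_stack", "frame_interval must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("movie_stack: %d frames of %d x %d px, %.3g um/px, %.3g s/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Specify a synthetic imaging scene
#'
#' Geometry for the image generators: myotubes as ribbons around centerline
#' polylines, nuclei as disks (optionally assigned to a tube and flagged as
#' high-BTX), and FISH puncta as small disks. All geometry is in
#' micrometres; `image_size` is in pixels as `c(nrow, ncol)`.
#'
#' @param image_size image shape in pixels, `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @param tubes list of `list(centerline = <n x 2 matrix of (x, y) um>,
#'   width = <um>)`.
#' @param nuclei data frame with columns `x`, `y`, `radius` (um) and
#'   optionally `tube` (index into `tubes`, NA for extra-tube nuclei) and
#'   `btx_high` (logical).
#' @param puncta data frame with columns `x`, `y`, `radius` (um) and
#'   optionally `intensity`.
#' @param background_level base intensity of every channel.
#' @param noise_sd additive Gaussian intensity noise.
#' @param btx_base mean BTX intensity of background-level nuclei.
#' @param btx_high_factor multiple of `btx_base` given to high-BTX nuclei.
#' @param texture_grain speckle grain size (px) used by the movie renderer.
#' @return a validated `scene_spec` object.
#' @export
scene_spec <- function(image_size = c(256L, 256L), pixel_size = 0.5,
                       tubes = list(), nuclei = NULL, puncta = NULL,
                       background_level = 10, noise_sd = 0,
                       btx_base = 100, btx_high_factor = 3,
                       texture_grain = 3) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L))
    .stop_invalid("scene_spec", "image_size must be c(rows, cols), each >= 8")
  if (pixel_size <= 0) .stop_invalid("scene_spec", "pixel_size must be > 0")
  ext <- c(image_size[2], image_size[1]) * pixel_size  # (x, y) extent in um
  for (tb in tubes) {
    if (!is.matrix(tb$centerline) || ncol(tb$centerline) != 2)
      .stop_invalid("scene_spec", "tube centerline must be an n x 2 matrix")
    if (!is.finite(tb$width) || tb$width <= 0)
      .stop_invalid("scene_spec", "tube width must be > 0")
    if (any(tb$centerline[, 1] < 0 | tb$centerline[, 1] > ext[1] |
            tb$centerline[, 2] < 0 | tb$centerline[, 2] > ext[2]))
      .stop_invalid("scene_spec", "tube centerline outside image bounds")
  }
  if (is.null(nuclei))
    nuclei <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  nuclei <- as.data.frame(nuclei)
  if (nrow(nuclei)) {
    if (is.null(nuclei$tube)) nuclei$tube <- NA_integer_
    if (is.null(nuclei$btx_high)) nuclei$btx_high <- FALSE
    if (any(nuclei$radius <= 0))
      .stop_invalid("scene_spec", "nucleus radii must be > 0")
    if (any(nuclei$x < 0 | nuclei$x > ext[1] | nuclei$y < 0 | nuclei$y > ext[2]))
      .stop_invalid("scene_spec", "nucleus center outside image bounds")
  } else {
    nuclei$tube <- integer(0); nuclei$btx_high <- logical(0)
  }
  if (is.null(puncta))
    puncta <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  puncta <- as.data.frame(puncta)
  if (nrow(puncta)) {
    if (is.null(puncta$intensity)) puncta$intensity <- 200
    if (any(puncta$radius <= 0))
      .stop_invalid("scene_spec", "punctum radii must be > 0")
  } else puncta$intensity <- numeric(0)
  structure(list(image_size = image_size, pixel_size = pixel_size,
                 tubes = tubes, nuclei = nuclei, puncta = puncta,
                 background_level = background_level, noise_sd = noise_sd,
                 btx_base = btx_base, btx_high_factor = btx_high_factor,
                 texture_grain = texture_grain),
            class = "scene_spec")
}

# pixel-center coordinate grids in micrometres: list(x = matrix, y = matrix)
.pixel_grid_um <- function(scene) {
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  x <- (seq_len(nc) - 0.5) * scene$pixel_size
  y <- (seq_len(nr) - 0.5) * scene$pixel_size
  list(x = matrix(x, nr, nc, byrow = TRUE), y = matrix(y, nr, nc))
}

# binary ribbon mask of all tubes (logical matrix)
.tube_mask <- function(scene) {
  g <- .pixel_grid_um(scene)
  m <- matrix(FALSE, scene$image_size[1], scene$image_size[2])
  for (tb in scene$tubes) {
    d <- .dist_polyline(as.vector(g$x), as.vector(g$y), tb$centerline)
    m <- m | matrix(d <= tb$width / 2, scene$image_size[1], scene$image_size[2])
  }
  m
}

# additive disk stamps; rows of df need x, y, radius (+ value column name)
.stamp_disks <- function(scene, df, value) {
  g <- .pixel_grid_um(scene)
  img <- matrix(0, scene$image_size[1], scene$image_size[2])
  for (i in seq_len(nrow(df))) {
    d2 <- (g$x - df$x[i])^2 + (g$y - df$y[i])^2
    img[d2 <= df$radius[i]^2] <- value[i]
  }
  img
}

# Gaussian blur with a separable kernel (sigma in px)
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
  conv1 <- function(m) {  # along rows (y direction)
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# band-limited speckle texture for the movie renderer
.speckle <- function(nr, nc, grain, seed) {
  z <- .with_seed(seed, matrix(runif(nr * nc, -1, 1), nr, nc))
  z <- .gauss_blur(z, grain / 2)
  z / max(abs(z))
}

# Raised-cosine low-pass keeping |k| < 0.45 cycles/px (roll-off from 0.30).
# The rendered base image is strictly band-limited, as a microscope PSF
# would make it, so Fourier-shifting it is an exact rigid translation.
.bandlimit <- function(img, k_pass = 0.30, k_stop = 0.45) {
  nr <- nrow(img); nc <- ncol(img)
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)] / nc
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)] / nr
  kr <- sqrt(outer(ky^2, rep(1, nc)) + outer(rep(1, nr), kx^2))
  H <- ifelse(kr <= k_pass, 1,
              ifelse(kr >= k_stop, 0,
                     0.5 * (1 + cos(pi * (kr - k_pass) / (k_stop - k_pass)))))
  Re(fft(fft(img) * H, inverse = TRUE)) / (nr * nc)
}

#' Band-limited speckle texture for PIV benchmarking
#'
#' The texture the movie renderer paints onto myotube ribbons, over the
#' full frame: Gaussian-smoothed uniform noise, low-passed below Nyquist so
#' that [shift_image()] translates it exactly.
#'
#' @param nrow,ncol frame size in px.
#' @param grain speckle grain size in px.
#' @param seed integer seed.
#' @param mean,amplitude intensity offset and scale.
#' @return numeric matrix.
#' @export
generate_texture <- function(nrow, ncol, grain = 3, seed = 1L,
                             mean = 100, amplitude = 50) {
  .bandlimit(.speckle(nrow, ncol, grain, seed) * amplitude + mean)
}

#' Rigid subpixel translation of a band-limited image
#'
#' Exact circular translation via the Fourier shift theorem. Intended for
#' images from [generate_texture()] or the movie renderer, whose spectra
#' vanish near Nyquist.
#'
#' @param img numeric matrix.
#' @param dx,dy translation in px (content moves rightward/downward for
#'   positive values).
#' @return translated matrix.
#' @export
shift_image <- function(img, dx, dy = 0) .fourier_shift(img, dx, dy)

# rigid subpixel translation via the Fourier shift theorem (periodic)
.fourier_shift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)] / nc
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)] / nr
  # Nyquist row/col must stay real under non-integer shifts
  if (nc %% 2 == 0) kx[nc / 2 + 1] <- if (abs(dx - round(dx)) < 1e-12) kx[nc / 2 + 1] else 0
  if (nr %% 2 == 0) ky[nr / 2 + 1] <- if (abs(dy - round(dy)) < 1e-12) ky[nr / 2 + 1] else 0
  ph <- exp(-2i * pi * outer(ky * dy, rep(1, nc)) -
            2i * pi * outer(rep(1, nr), kx * dx))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (nr * nc)
}

#' Render a synthetic contracting-myotube movie
#'
#' Builds a fixed speckle-textured scene (soft-edged tube ribbons with
#' embedded nucleus disks over a flat background) and translates it rigidly
#' along the first tube's axis by the waveform's instantaneous displacement,
#' frame by frame. Subpixel translation uses the Fourier shift theorem, so
#' the rendered motion equals the requested waveform exactly and integer
#' shifts reproduce the source frame to floating-point accuracy. Per-frame
#' Gaussian noise is added afterwards.
#'
#' @param spec a [waveform_spec()] (temporal regime).
#' @param scene a [scene_spec()] with at least one tube and one nucleus.
#' @param seed integer seed fixing texture and noise.
#' @return list with `movie` (a [movie_stack()]) and `truth`: a list holding
#'   `displacement_um` (the exact displacement-magnitude trace every nucleus
#'   follows), `times`, `nuclei` (planted centers, um) and `axis`.
#' @export
generate_movie <- function(spec, scene, seed = 1L) {
  stopifnot(inherits(spec, "waveform_spec"), inherits(scene, "scene_spec"))
  if (length(scene$tubes) < 1L || nrow(scene$nuclei) < 1L)
    .stop_invalid("scene_spec", "movie scenes need >= 1 tube with >= 1 nucleus")
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  n <- round(spec$duration / spec$sample_interval)
  t <- (seq_len(n) - 1) * spec$sample_interval
  s_um <- .waveform_value(spec, t)
  axis <- .polyline_axis(scene$tubes[[1]]$centerline)
  max_px <- max(abs(s_um)) / scene$pixel_size
  # the moving texture must not run off the frame
  tube_px <- .tube_mask(scene)
  rows <- range(which(rowSums(tube_px) > 0)); cols <- range(which(colSums(tube_px) > 0))
  margin <- min(rows[1] - 1, nr - rows[2], cols[1] - 1, nc - cols[2])
  if (max_px > margin)
    .stop_invalid("generate_movie",
                  sprintf("peak displacement %.1f px exceeds %.0f px image margin",
                          max_px, margin))
  ribbon <- .gauss_blur(tube_px * 1, 1)      # soft edge limits ringing
  tex <- .speckle(nr, nc, scene$texture_grain, seed)
  nuc_soft <- if (nrow(scene$nuclei))
    .gauss_blur(.stamp_disks(scene, scene$nuclei, rep(1, nrow(scene$nuclei))), 1)
    else 0
  # nuclei render as smooth bright domes: the speckle is suppressed under
  # them, as in brightfield, so their photometric centroid is well defined
  base <- scene$background_level +
    ribbon * (50 + 40 * tex * (1 - nuc_soft)) + 60 * nuc_soft
  base <- .bandlimit(base)
  frames <- vector("list", n)
  noise <- if (scene$noise_sd > 0)
    .with_seed(seed + 1L, replicate(n, matrix(rnorm(nr * nc, 0, scene$noise_sd), nr, nc),
                                    simplify = FALSE))
    else NULL
  for (k in seq_len(n)) {
    d_px <- s_um[k] / scene$pixel_size
    fr <- if (abs(d_px) < 1e-12) base else
      .fourier_shift(base, d_px * axis[1], d_px * axis[2])
    if (!is.null(noise)) fr <- fr + noise[[k]]
    frames[[k]] <- fr
  }
  list(movie = movie_stack(frames, scene$pixel_size, spec$sample_interval),
       truth = list(displacement_um = abs(s_um), times = t,
                    nuclei = scene$nuclei[, c("x", "y")], axis = axis))
}

#' Render synthetic fluorescence channels with ground truth
#'
#' Produces the four-channel still image the measurement modules consume:
#' alpha-actinin (filled tube ribbons), DAPI (nucleus disks), BTX
#' (per-nucleus disk intensities from a two-level design: `btx_base` for
#' background nuclei, `btx_base * btx_high_factor` for high nuclei) and
#' FISH (puncta disks). The returned ground truth records every quantity
#' the morphometry and scoring modules are expected to recover.
#'
#' @param scene a [scene_spec()].
#' @param seed integer seed fixing the intensity noise.
#' @param min_separation_um minimum allowed center distance between two
#'   nuclei of the same tube, as a multiple of the sum of their radii plus
#'   this many micrometres; closer pairs raise an error so counts stay
#'   unambiguous.
#' @return list with `channels` (named list of matrices: `actinin`, `dapi`,
#'   `btx`, `fish`) and `truth` (tube widths, nuclei table, high-BTX
#'   proportion, puncta table, per-tube spacing statistics).
#' @export
generate_morphology_image <- function(scene, seed = 1L, min_separation_um = 1) {
  stopifnot(inherits(scene, "scene_spec"))
  nuc <- scene$nuclei
  if (nrow(nuc) >= 2L) {
    for (tb in unique(stats::na.omit(nuc$tube))) {
      idx <- which(!is.na(nuc$tube) & nuc$tube == tb)
      if (length(idx) < 2L) next
      for (a in idx) for (b in idx) if (a < b) {
        d <- sqrt((nuc$x[a] - nuc$x[b])^2 + (nuc$y[a] - nuc$y[b])^2)
        if (d < nuc$radius[a] + nuc$radius[b] + min_separation_um)
          .stop_invalid("scene_spec",
                        sprintf("nuclei %d and %d of tube %d closer than the minimum separation", a, b, tb))
      }
    }
  }
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  bg <- scene$background_level
  actinin <- bg + 150 * .tube_mask(scene)
  dapi <- bg + if (nrow(nuc)) .stamp_disks(scene, nuc, rep(150, nrow(nuc))) else 0
  btx_lvl <- scene$btx_base * ifelse(nuc$btx_high, scene$btx_high_factor, 1)
  btx <- bg + if (nrow(nuc)) .stamp_disks(scene, nuc, btx_lvl) else 0
  fish <- bg + if (nrow(scene$puncta))
    .stamp_disks(scene, scene$puncta, scene$puncta$intensity) else 0
  channels <- list(actinin = actinin, dapi = dapi, btx = btx, fish = fish)
  if (scene$noise_sd > 0)
    channels <- .with_seed(seed, lapply(channels, function(ch)
      ch + matrix(rnorm(nr * nc, 0, scene$noise_sd), nr, nc)))
  # per-tube nuclei spacing along the centerline
  spacing <- lapply(seq_along(scene$tubes), function(ti) {
    idx <- which(!is.na(nuc$tube) & nuc$tube == ti)
    if (length(idx) < 2L)
      return(data.frame(tube = ti, mean_gap_um = NA_real_, cov = NA_real_))
    arc <- sort(.project_polyline(nuc$x[idx], nuc$y[idx],
                                  scene$tubes[[ti]]$centerline)$arc)
    gaps <- diff(arc)
    data.frame(tube = ti, mean_gap_um = mean(gaps),
               cov = .pop_sd(gaps) / mean(gaps))
  })
  truth <- list(
    tube_widths = vapply(scene$tubes, `[[`, numeric(1), "width"),
    nuclei = nuc,
    high_btx_proportion = if (nrow(nuc)) mean(nuc$btx_high) else NA_real_,
    puncta = scene$puncta,
    spacing = do.call(rbind, spacing),
    pixel_size = scene$pixel_size)
  list(channels = channels, truth = truth)
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Builds cycle-threshold values for a control and a treated group such
#' that the expected relative expression `2^-ddCt` of each gene equals
#' `2^log2_fc`. A housekeeping gene is included for every sample.
#'
#' @param genes character vector of gene names.
#' @param log2_fc true log2 fold change per gene (treated vs control).
#' @param noise_sd Gaussian noise added to every measured Ct, cycles.
#' @param seed integer seed.
#' @param n_replicates samples per group.
#' @param housekeeping housekeeping gene name.
#' @return data frame with columns `sample`, `group`, `gene`, `ct`.
#' @export
generate_ct_table <- function(genes, log2_fc, noise_sd = 0, seed = 1L,
                              n_replicates = 3L, housekeeping = "HPRT") {
  stopifnot(length(genes) == length(log2_fc))
  if (noise_sd < 0) .stop_invalid("generate_ct_table", "noise_sd must be >= 0")
  groups <- c("control", "treated")
  rows <- expand.grid(rep = seq_len(n_replicates), group = groups,
                      gene = c(genes, housekeeping), stringsAsFactors = FALSE)
  base_ct <- 25; hk_ct <- 20
  eff <- stats::setNames(c(log2_fc, 0), c(genes, housekeeping))
  ct <- ifelse(rows$gene == housekeeping, hk_ct,
               base_ct - ifelse(rows$group == "treated", eff[rows$gene], 0))
  if (noise_sd > 0) ct <- ct + .with_seed(seed, rnorm(length(ct), 0, noise_sd))
  data.frame(sample = paste0(rows$group, "_", rows$rep), group = rows$group,
             gene = rows$gene, ct = ct, stringsAsFactors = FALSE)
}
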