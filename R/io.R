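# TIFF and CSV I/O. Calibration always comes from the config/arguments,
# never from TIFF tags (tag dialects are too inconsistent across vendors).

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file with one grayscale page per frame.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, pixel_size, frame_interval) {
  if (!file.exists(path)) stop("movie not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, .page_to_gray)
  movie_stack(frames, pixel_size, frame_interval)
}

#' Write a movie stack as a multi-page TIFF
#'
#' Frames are jointly rescaled to `[0, 1]` and stored as 16-bit grayscale
#' (the PIV correlation is invariant to affine intensity rescaling).
#'
#' @param stack a [movie_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  lo <- min(vapply(stack$frames, min, numeric(1)))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  sc <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(stack$frames, function(f) (f - lo) / sc), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read co-registered single-page channel TIFFs
#'
#' @param paths named character vector of per-channel TIFF paths.
#' @return named list of matrices; an error names the mismatched channels
#'   when shapes differ.
#' @export
read_channels <- function(paths) {
  chans <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("channel not found: ", p, call. = FALSE)
    .page_to_gray(tiff::readTIFF(p))
  })
  d0 <- dim(chans[[1]])
  for (nm in names(chans))
    if (!all(dim(chans[[nm]]) == d0))
      stop(sprintf("channel '%s' shape (%d x %d) differs from '%s' (%d x %d)",
                   nm, nrow(chans[[nm]]), ncol(chans[[nm]]),
                   names(chans)[1], d0[1], d0[2]), call. = FALSE)
  chans
}

#' Write channel matrices as single-page TIFFs
#'
#' @param channels named list of matrices.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return named vector of written paths.
#' @export
write_channels <- function(channels, dir, prefix = "channel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(names(channels), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    m <- channels[[nm]]
    lo <- min(m); hi <- max(m)
    tiff::writeTIFF((m - lo) / if (hi > lo) hi - lo else 1, p,
                    bits.per.sample = 16L)
    p
  }, character(1))
  out
}

#' Write scene geometry as a JSON sidecar
#'
#' Serializes a [scene_spec()]'s geometry (tubes, nuclei, puncta,
#' calibration) next to rendered images so downstream tools can recover
#' the ground truth without re-running the generator.
#'
#' @param scene a [scene_spec()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "scene_spec"))
  obj <- list(
    image_size = scene$image_size,
    pixel_size = scene$pixel_size,
    tubes = lapply(scene$tubes, function(tb)
      list(centerline = unname(apply(tb$centerline, 1, c, simplify = FALSE)),
           width = tb$width)),
    nuclei = scene$nuclei,
    puncta = scene$puncta,
    background_level = scene$background_level,
    noise_sd = scene$noise_sd,
    btx_base = scene$btx_base,
    btx_high_factor = scene$btx_high_factor)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.page_to_gray <- function(page) {
  if (length(dim(page)) == 3L) page <- page[, , 1]  # first channel of RGB(A)
  as.matrix(page)
}

# CSV with '#'-prefixed metadata lines (config hash, package version)
.write_csv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (m in names(meta)) writeLines(sprintf("# %s: %s", m, meta[[m]]), con)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) signif(col, 9) else col)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a displacement trace as CSV
#'
#' Columns `t`, `displacement_um`, `velocity_um_s` (velocity aligned with
#' the interval ending at each sample; first entry NA), with metadata in
#' `#` comment lines.
#'
#' @param trace a [displacement_trace()].
#' @param path output path.
#' @param meta named character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = character()) {
  stopifnot(inherits(trace, "displacement_trace"))
  df <- data.frame(t = trace$times, displacement_um = trace$displacement,
                   velocity_um_s = c(NA, trace$velocity))
  meta <- c(meta, source = trace$source,
            truncated = as.character(trace$truncated))
  .write_csv_meta(df, path, meta)
}

#' Read a displacement trace CSV
#'
#' @param path CSV written by [write_trace_csv()].
#' @return a [displacement_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  displacement_trace(df$t, df$displacement_um,
                     velocity = df$velocity_um_s[-1],
                     source = basename(path))
}
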