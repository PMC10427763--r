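#' Background BTX intensity from the modal histogram bin
#'
#' Histograms the per-nucleus mean BTX intensities over their observed
#' range and returns the center of the most populated bin (ties resolve to
#' the lower bin) — the background level most nuclei sit at.
#'
#' @param means per-nucleus mean BTX intensities (>= 10 values; pool images
#'   when fewer nuclei are available).
#' @param histogram_bins number of bins (default 64).
#' @return background intensity level.
#' @export
btx_background <- function(means, histogram_bins = 64L) {
  means <- as.numeric(means)
  if (length(means) < 10L)
    stop("need >= 10 nuclei for a stable modal bin; pool images first",
         call. = FALSE)
  if (diff(range(means)) == 0) {
    warning("all nucleus means identical; returning that value")
    return(means[1])
  }
  breaks <- seq(min(means), max(means), length.out = histogram_bins + 1L)
  counts <- graphics::hist(means, breaks = breaks, plot = FALSE)$counts
  i <- which.max(counts)                     # which.max takes the lower tie
  (breaks[i] + breaks[i + 1L]) / 2
}

#' Classify high-BTX (AChR-positive) nuclei
#'
#' A nucleus is AChR-positive when its mean BTX intensity strictly exceeds
#' `factor` times the background level (a value at exactly the threshold is
#' not flagged).
#'
#' @param records data frame with a `mean_btx` column (e.g. nucleus table
#'   with intensities attached).
#' @param background background level, e.g. from [btx_background()].
#' @param factor threshold multiple (default 2).
#' @return list: `records` with logical `is_high` added, and `proportion`
#'   of high nuclei.
#' @export
classify_high_btx <- function(records, background, factor = 2.0) {
  stopifnot(is.data.frame(records), "mean_btx" %in% names(records))
  if (!(background > 0)) stop("background must be > 0", call. = FALSE)
  records$is_high <- records$mean_btx > factor * background
  list(records = records,
       proportion = if (nrow(records)) mean(records$is_high) else NA_real_)
}

#' Mean channel intensity within each labelled nucleus
#'
#' @param channel raw intensity matrix.
#' @param label_matrix integer labels (e.g. from [label_components()]).
#' @return data frame `nucleus_id`, `mean_btx`.
#' @export
nucleus_mean_intensity <- function(channel, label_matrix) {
  stopifnot(all(dim(channel) == dim(label_matrix)))
  ids <- sort(unique(label_matrix[label_matrix > 0]))
  data.frame(nucleus_id = ids,
             mean_btx = vapply(ids, function(l)
               mean(channel[label_matrix == l]), numeric(1)))
}

#' Shape descriptors of one AChR cluster
#'
#' Area from the pixel count, perimeter from the 8-connected boundary
#' chain (diagonal steps weigh sqrt(2)), major axis from the second-moment
#' ellipse fit; circularity `4*pi*area / perimeter^2` and roundness
#' `4*area / (pi * major_axis^2)`.
#'
#' @param cluster_mask logical mask holding exactly one connected
#'   component.
#' @param pixel_size micrometres per pixel.
#' @param min_reliable_px components smaller than this get
#'   `reliable = FALSE` (shape metrics on a handful of pixels are noise).
#' @return list: `area_um2`, `perimeter_um`, `circularity`, `roundness`,
#'   `major_axis_um`, `reliable`.
#' @export
cluster_shape <- function(cluster_mask, pixel_size, min_reliable_px = 5L) {
  m <- cluster_mask != 0
  if (!any(m)) stop("empty cluster mask", call. = FALSE)
  lab <- label_components(m)
  if (max(lab) > 1L)
    stop("mask holds several components; split them and call per cluster",
         call. = FALSE)
  npx <- sum(m)
  area <- npx * pixel_size^2
  per <- .chain_perimeter(m) * pixel_size
  idx <- which(m)
  ys <- ((idx - 1L) %% nrow(m)) + 1L
  xs <- ((idx - 1L) %/% nrow(m)) + 1L
  # central second moments with the 1/12 per-pixel extent correction, so a
  # digitized rectangle reproduces its continuous-moment axis lengths
  mxx <- mean((xs - mean(xs))^2) + 1 / 12
  myy <- mean((ys - mean(ys))^2) + 1 / 12
  mxy <- mean((xs - mean(xs)) * (ys - mean(ys)))
  lam1 <- (mxx + myy) / 2 + sqrt(((mxx - myy) / 2)^2 + mxy^2)
  major <- 4 * sqrt(lam1) * pixel_size
  list(area_um2 = area,
       perimeter_um = per,
       circularity = if (per > 0) 4 * pi * area / per^2 else NA_real_,
       roundness = if (major > 0) 4 * area / (pi * major^2) else NA_real_,
       major_axis_um = major,
       reliable = npx >= min_reliable_px)
}

# perimeter of a single component: boundary chain length via ocontour
.chain_perimeter <- function(m) {
  if (sum(m) == 1L) return(4)  # lone pixel: its own square boundary
  oc <- EBImage::ocontour(EBImage::Image(matrix(as.integer(m), nrow(m), ncol(m))))
  ctr <- oc[[1]]
  if (nrow(ctr) < 2L) return(4)
  steps <- sqrt(rowSums((ctr - ctr[c(2:nrow(ctr), 1), ])^2))
  sum(steps)
}

#' Perinuclear region of a myotube
#'
#' All tube-mask pixels whose arc-length projection onto the centerline
#' lies within `half_length_um` of the nucleus centroid's projection — the
#' band in which perinuclear mRNA spots are counted.
#'
#' @param centroid `c(x, y)` nucleus centroid, micrometres.
#' @param centerline m x 2 polyline, micrometres.
#' @param tube_mask logical myotube mask.
#' @param pixel_size micrometres per pixel.
#' @param half_length_um band half-length (default 50).
#' @param max_centroid_dist_um error when the centroid is farther than
#'   this from the centerline.
#' @return logical region mask; attribute `degenerate` is `TRUE` when the
#'   requested band is empty or a single cross-section.
#' @export
perinuclear_region <- function(centroid, centerline, tube_mask, pixel_size,
                               half_length_um = 50,
                               max_centroid_dist_um = 50) {
  stopifnot(length(centroid) == 2L)
  p0 <- .project_polyline(centroid[1], centroid[2], centerline)
  if (p0$dist > max_centroid_dist_um)
    stop(sprintf("centroid lies %.1f um from the centerline (limit %.1f)",
                 p0$dist, max_centroid_dist_um), call. = FALSE)
  m <- tube_mask != 0
  idx <- which(m)
  ys <- (((idx - 1L) %% nrow(m)) + 1L - 0.5) * pixel_size
  xs <- (((idx - 1L) %/% nrow(m)) + 1L - 0.5) * pixel_size
  arc <- .project_polyline(xs, ys, centerline)$arc
  keep <- abs(arc - p0$arc) <= half_length_um
  region <- matrix(FALSE, nrow(m), ncol(m))
  region[idx[keep]] <- TRUE
  attr(region, "degenerate") <- sum(region) < 2 / pixel_size
  region
}

#' Count FISH spots within a region
#'
#' Spots are 8-connected components of the binarized FISH channel with an
#' area in `[min_area_px, max_area_px]`; a spot belongs to the region when
#' its centroid (rounded to the nearest pixel) lies inside it, so boundary
#' straddlers are counted exactly once. The density normalizer is supplied
#' by the caller: myotube-region area for receptor-subunit and filamin
#' probes, myonucleus area for myosin heavy-chain probes.
#'
#' @param fish_mask binarized FISH channel.
#' @param region_mask logical region of interest (same shape).
#' @param min_area_px,max_area_px spot size filter in px.
#' @param normalizer_um2 area (um^2) to normalize the count by; optional.
#' @return list: `spot_count`, `density_per_um2` (NA without normalizer),
#'   `spots` (centroid table).
#' @export
count_spots <- function(fish_mask, region_mask, min_area_px = 1L,
                        max_area_px = Inf, normalizer_um2 = NA_real_) {
  stopifnot(all(dim(fish_mask) == dim(region_mask)))
  lab <- label_components(fish_mask != 0)
  tab <- .component_table(lab)
  tab <- tab[tab$area_px >= min_area_px & tab$area_px <= max_area_px, ,
             drop = FALSE]
  reg <- region_mask != 0
  if (nrow(tab)) {
    rr <- pmin(pmax(round(tab$cy), 1L), nrow(reg))
    cc <- pmin(pmax(round(tab$cx), 1L), ncol(reg))
    tab$in_region <- reg[cbind(rr, cc)]
  } else tab$in_region <- logical(0)
  cnt <- sum(tab$in_region)
  list(spot_count = cnt,
       density_per_um2 = cnt / normalizer_um2,
       spots = tab[tab$in_region, , drop = FALSE])
}
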