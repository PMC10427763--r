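# --- binary-image primitives ----------------------------------------------

#' Label connected components of a binary mask
#'
#' 8-connectivity labelling built on EBImage's 4-connected `bwlabel` by
#' merging labels that touch diagonally (union-find).
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(m))
  if (connectivity == 4L || max(lab) <= 1L) return(.relabel(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # / diagonal
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_along(parent), find, integer(1))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  .relabel(lab)
}

.relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  lut <- integer(max(u)); lut[u] <- seq_along(u)
  lab[lab > 0] <- lut[lab[lab > 0]]
  lab
}

# per-label pixel stats: area, centroid (x = col, y = row)
.component_table <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx))
    return(data.frame(label = integer(0), area_px = integer(0),
                      cx = numeric(0), cy = numeric(0)))
  l <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  data.frame(label = sort(unique(l)),
             area_px = as.integer(table(l)),
             cx = as.numeric(tapply(cc, l, mean)),
             cy = as.numeric(tapply(rr, l, mean)))
}

# 8-neighbor shifts of a logical matrix (padded with FALSE)
.shift_mask <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton
.skeletonize <- function(mask) {
  P <- matrix(mask != 0, nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      n2 <- .shift_mask(P, 1, 0);  n3 <- .shift_mask(P, 1, -1)
      n4 <- .shift_mask(P, 0, -1); n5 <- .shift_mask(P, -1, -1)
      n6 <- .shift_mask(P, -1, 0); n7 <- .shift_mask(P, -1, 1)
      n8 <- .shift_mask(P, 0, 1);  n9 <- .shift_mask(P, 1, 1)
      B <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      A <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
           (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
      if (sub == 1) {
        c1 <- !(n2 & n4 & n6); c2 <- !(n4 & n6 & n8)
      } else {
        c1 <- !(n2 & n4 & n8); c2 <- !(n2 & n6 & n8)
      }
      del <- P & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) { P[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  P
}

# skeleton-neighbor count (8-neighborhood)
.skel_degree <- function(S) {
  .shift_mask(S, 1, 0) + .shift_mask(S, -1, 0) + .shift_mask(S, 0, 1) +
    .shift_mask(S, 0, -1) + .shift_mask(S, 1, 1) + .shift_mask(S, 1, -1) +
    .shift_mask(S, -1, 1) + .shift_mask(S, -1, -1)
}

# Prune endpoint branches shorter than the local tube width (2 x distance
# map at the junction they attach to). Spur artifacts of thinning would
# otherwise inflate the skeleton length and deflate the width estimate.
.prune_skeleton <- function(S, mask, rounds = 2L) {
  dm <- as.matrix(EBImage::distmap(matrix(as.integer(mask != 0),
                                          nrow(mask), ncol(mask))))
  nbr_off <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                   dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  for (round in seq_len(rounds)) {
    deg <- .skel_degree(S)
    eps <- which(S & deg == 1)
    pruned_any <- FALSE
    for (e in eps) {
      r0 <- ((e - 1L) %% nrow(S)) + 1L; c0 <- ((e - 1L) %/% nrow(S)) + 1L
      path <- list(c(r0, c0))
      prev <- c(NA, NA); cur <- c(r0, c0); len <- 0
      repeat {
        nb <- NULL
        for (k in seq_len(8)) {
          rr <- cur[1] + nbr_off[k, 1]; cc <- cur[2] + nbr_off[k, 2]
          if (rr < 1 || rr > nrow(S) || cc < 1 || cc > ncol(S)) next
          if (!S[rr, cc]) next
          if (!is.na(prev[1]) && rr == prev[1] && cc == prev[2]) next
          nb <- rbind(nb, c(rr, cc))
        }
        if (is.null(nb) || nrow(nb) != 1L) break  # junction, end, or fork
        step <- nb[1, ]
        len <- len + sqrt(sum((step - cur)^2))
        if (deg[step[1], step[2]] >= 3) { cur <- step; break }
        path[[length(path) + 1L]] <- step
        prev <- cur; cur <- step
        if (len > 2 * max(dm)) break
      }
      local_w <- 2 * dm[cur[1], cur[2]]
      if (len < local_w && length(path) < sum(S)) {
        for (p in path) S[p[1], p[2]] <- FALSE
        pruned_any <- TRUE
      }
    }
    if (!pruned_any) break
  }
  S
}

# skeleton length in px: 4-adjacent steps count 1, diagonal steps sqrt(2);
# diagonals shortcutting an existing 4-path are not double counted
.skeleton_length_px <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  H <- sum(S[, -nc] & S[, -1])
  V <- sum(S[-nr, ] & S[-1, ])
  d1 <- S[-nr, -nc] & S[-1, -1] & !(S[-1, -nc] | S[-nr, -1])
  d2 <- S[-nr, -1] & S[-1, -nc] & !(S[-1, -1] | S[-nr, -nc])
  H + V + sqrt(2) * (sum(d1) + sum(d2))
}

# --- module operations -----------------------------------------------------

#' Preprocess a fluorescence channel to a binary mask
#'
#' Maximum-intensity z-projection (for 3D stacks), background subtraction
#' by grayscale morphological opening with a disc (white top-hat), Otsu
#' thresholding, and small-object removal.
#'
#' @param raw 2D matrix or 3D array (z last).
#' @param background_radius disc radius in px for the opening-based
#'   background estimate; 0 disables background subtraction.
#' @param min_area_px discard foreground components smaller than this.
#' @return logical mask with the preprocessing parameters attached as the
#'   `provenance` attribute. Empty or constant inputs yield an empty mask
#'   with a warning.
#' @export
preprocess_channel <- function(raw, background_radius = 50, min_area_px = 20) {
  if (length(dim(raw)) == 3L) raw <- apply(raw, c(1, 2), max)
  stopifnot(is.matrix(raw))
  prov <- list(background_radius = background_radius, min_area_px = min_area_px)
  if (diff(range(raw)) == 0) {
    warning("constant image: returning an empty mask")
    out <- matrix(FALSE, nrow(raw), ncol(raw))
    attr(out, "provenance") <- prov
    return(out)
  }
  img <- raw
  if (background_radius > 0) {
    side <- 2 * floor(background_radius) + 1
    brush <- EBImage::makeBrush(side, shape = "disc")
    sc <- range(img)
    nimg <- (img - sc[1]) / (sc[2] - sc[1])
    bg <- EBImage::dilate(EBImage::erode(EBImage::Image(nimg), brush), brush)
    img <- nimg - as.matrix(bg)
  } else {
    sc <- range(img)
    img <- (img - sc[1]) / (sc[2] - sc[1])
  }
  img <- pmax(img, 0)
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, max(img)))
  mask <- img > thr
  if (min_area_px > 0 && any(mask)) {
    lab <- label_components(mask)
    tab <- .component_table(lab)
    small <- tab$label[tab$area_px < min_area_px]
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  attr(mask, "provenance") <- prov
  mask
}

#' Myotube area, skeleton length and average width
#'
#' The proportional area is the foreground fraction of the image; the
#' skeleton is the pruned medial-axis (thinning) centerline, its length the
#' sum of inter-pixel steps (1 for 4-steps, sqrt(2) diagonal); average
#' width is foreground area divided by skeleton length.
#'
#' @param actinin_mask logical mask of the myotube stain.
#' @param pixel_size micrometres per pixel.
#' @return list: `proportional_area`, `skeleton_length_um`,
#'   `average_width_um`, plus the skeleton mask (`skeleton`).
#' @export
width_metrics <- function(actinin_mask, pixel_size) {
  m <- actinin_mask != 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  S <- .prune_skeleton(.skeletonize(m), m)
  len_px <- .skeleton_length_px(S)
  area_um2 <- sum(m) * pixel_size^2
  list(proportional_area = mean(m),
       skeleton_length_um = len_px * pixel_size,
       average_width_um = if (len_px > 0) area_um2 / (len_px * pixel_size) else NA_real_,
       skeleton = S)
}

#' Identify myonuclei and their density
#'
#' Nuclei are 8-connected components of the DAPI mask above a minimum
#' area; a nucleus is a myonucleus when at least `min_overlap` of its area
#' lies within the actinin mask (boundary inclusive). Density is
#' myonuclei per mm^2 of image.
#'
#' @param dapi_mask,actinin_mask logical masks of the same shape.
#' @param pixel_size micrometres per pixel.
#' @param min_overlap overlap fraction threshold (default 0.5).
#' @param min_area_px discard DAPI components smaller than this.
#' @return list: `nuclei` (data frame with centroid `cx`, `cy` in px,
#'   `area_px`, `overlap`, `is_myonucleus`) and `density_per_mm2`.
#' @export
assign_myonuclei <- function(dapi_mask, actinin_mask, pixel_size,
                             min_overlap = 0.5, min_area_px = 20) {
  stopifnot(all(dim(dapi_mask) == dim(actinin_mask)))
  lab <- label_components(dapi_mask != 0)
  tab <- .component_table(lab)
  tab <- tab[tab$area_px >= min_area_px, , drop = FALSE]
  act <- actinin_mask != 0
  tab$overlap <- vapply(tab$label, function(l) {
    sel <- lab == l
    sum(act[sel]) / sum(sel)
  }, numeric(1))
  tab$is_myonucleus <- tab$overlap >= min_overlap
  img_mm2 <- prod(dim(dapi_mask)) * pixel_size^2 / 1e6
  list(nuclei = tab,
       density_per_mm2 = sum(tab$is_myonucleus) / img_mm2)
}

#' Myonuclei spacing along a myotube
#'
#' Centroids are projected to their arc-length position along the tube
#' centerline; neighbor distances are the consecutive arc-length gaps after
#' sorting. Uniformity is the coefficient of variation of the gaps
#' (population SD / mean). `method = "euclidean"` instead takes straight-
#' line distances between arc-order neighbors.
#'
#' @param centroids n x 2 matrix of (x, y) positions in micrometres.
#' @param centerline m x 2 polyline in micrometres.
#' @param method `"arclength"` (default) or `"euclidean"`.
#' @return list: `mean_distance_um`, `cov`, `gaps_um`.
#' @export
nuclei_spacing <- function(centroids, centerline, method = c("arclength",
                                                             "euclidean")) {
  method <- match.arg(method)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2L)
    stop("need at least 2 nuclei to measure spacing", call. = FALSE)
  proj <- .project_polyline(centroids[, 1], centroids[, 2], centerline)
  o <- order(proj$arc)
  gaps <- if (method == "arclength") diff(proj$arc[o])
          else sqrt(rowSums(diff(centroids[o, , drop = FALSE])^2))
  mg <- mean(gaps)
  if (mg == 0) stop("zero mean neighbor distance: CoV undefined", call. = FALSE)
  list(mean_distance_um = mg, cov = .pop_sd(gaps) / mg, gaps_um = gaps)
}

#' Extract an ordered centerline polyline from a mask
#'
#' Skeletonizes the largest component of the mask, prunes spurs, and walks
#' the skeleton from one endpoint to produce an ordered polyline in
#' micrometre coordinates — the centerline the spacing and perinuclear
#' operations consume when no ground-truth geometry is available.
#'
#' @param mask logical myotube mask.
#' @param pixel_size micrometres per pixel.
#' @return k x 2 matrix of (x, y) micrometre coordinates along the tube.
#' @export
mask_centerline <- function(mask, pixel_size) {
  m <- mask != 0
  if (!any(m)) stop("empty mask", call. = FALSE)
  lab <- label_components(m)
  tab <- .component_table(lab)
  m <- lab == tab$label[which.max(tab$area_px)]
  S <- .prune_skeleton(.skeletonize(m), m)
  deg <- .skel_degree(S)
  eps <- which(S & deg == 1)
  start <- if (length(eps)) eps[1] else which(S)[1]
  nr <- nrow(S)
  cur <- c(((start - 1L) %% nr) + 1L, ((start - 1L) %/% nr) + 1L)
  visited <- matrix(FALSE, nr, ncol(S))
  path <- matrix(NA_real_, sum(S), 2)
  nbr_off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  k <- 0L
  repeat {
    k <- k + 1L
    visited[cur[1], cur[2]] <- TRUE
    path[k, ] <- c(cur[2], cur[1])   # (x, y) px
    nxt <- NULL
    for (q in seq_len(8)) {
      rr <- cur[1] + nbr_off[q, 1]; cc <- cur[2] + nbr_off[q, 2]
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(S)) next
      if (S[rr, cc] && !visited[rr, cc]) { nxt <- c(rr, cc); break }
    }
    if (is.null(nxt)) break
    cur <- nxt
  }
  # pixel centers sit at (index - 0.5) * pixel_size in micrometre coordinates
  (path[seq_len(k), , drop = FALSE] - 0.5) * pixel_size
}
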