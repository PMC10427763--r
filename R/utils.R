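# shared internal helpers: seeding, bilinear interpolation, geometry

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.stop_invalid <- function(what, msg) {
  stop(sprintf("invalid %s: %s", what, msg), call. = FALSE)
}

# Bilinear interpolation of Z (length(yg) x length(xg)) at points (xp, yp).
# Points outside the grid return NA unless clamp = TRUE, in which case
# coordinates are clamped to the hull (nearest-edge extrapolation).
.bilinear <- function(xg, yg, Z, xp, yp, clamp = FALSE) {
  if (clamp) {
    xp <- pmin(pmax(xp, xg[1]), xg[length(xg)])
    yp <- pmin(pmax(yp, yg[1]), yg[length(yg)])
  }
  out <- rep(NA_real_, length(xp))
  # a strict boundary test would reject points sitting on the hull edge up
  # to rounding noise, so admit (and clamp) within a relative tolerance
  tx <- 1e-9 * max(1, abs(xg[length(xg)]))
  ty <- 1e-9 * max(1, abs(yg[length(yg)]))
  ok <- xp >= xg[1] - tx & xp <= xg[length(xg)] + tx &
    yp >= yg[1] - ty & yp <= yg[length(yg)] + ty &
    is.finite(xp) & is.finite(yp)
  if (any(ok)) {
    xc <- pmin(pmax(xp[ok], xg[1]), xg[length(xg)])
    yc <- pmin(pmax(yp[ok], yg[1]), yg[length(yg)])
    if (length(xg) == 1L) { ix <- rep(1L, length(xc)); wx <- 0; nrS <- 0L }
    else {
      ix <- pmin(pmax(findInterval(xc, xg), 1L), length(xg) - 1L)
      wx <- (xc - xg[ix]) / (xg[ix + 1L] - xg[ix]); nrS <- nrow(Z)
    }
    if (length(yg) == 1L) { iy <- rep(1L, length(yc)); wy <- 0; dyS <- 0L }
    else {
      iy <- pmin(pmax(findInterval(yc, yg), 1L), length(yg) - 1L)
      wy <- (yc - yg[iy]) / (yg[iy + 1L] - yg[iy]); dyS <- 1L
    }
    nr <- nrow(Z)
    i00 <- (ix - 1L) * nr + iy
    out[ok] <- (1 - wy) * ((1 - wx) * Z[i00] + wx * Z[i00 + nrS]) +
      wy * ((1 - wx) * Z[i00 + dyS] + wx * Z[i00 + nrS + dyS])
  }
  out
}

# Sample image (matrix, rows = y, cols = x) at subpixel positions; pixel
# centers sit at integer coordinates 1..ncol / 1..nrow.
.sample_image <- function(img, xp, yp, fill = NA_real_) {
  v <- .bilinear(seq_len(ncol(img)), seq_len(nrow(img)), img, xp, yp)
  v[is.na(v)] <- fill
  v
}

# --- polyline geometry (coordinates in any consistent unit) ----------------

# poly: n x 2 matrix of (x, y) vertices
.polyline_cumlen <- function(poly) {
  d <- sqrt(rowSums(diff(poly)^2))
  c(0, cumsum(d))
}

# Project points (px, py) onto a polyline. Returns list(arc, dist):
# arc-length position of the nearest point and the distance to it.
.project_polyline <- function(px, py, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 2)
  cum <- .polyline_cumlen(poly)
  n <- length(px)
  best_d2 <- rep(Inf, n)
  best_arc <- rep(NA_real_, n)
  for (i in seq_len(nrow(poly) - 1L)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    vx <- poly[i + 1L, 1] - ax; vy <- poly[i + 1L, 2] - ay
    L2 <- vx * vx + vy * vy
    if (L2 == 0) next
    t <- ((px - ax) * vx + (py - ay) * vy) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[i] + t[upd] * sqrt(L2)
  }
  list(arc = best_arc, dist = sqrt(best_d2))
}

# distance of points to a polyline (vectorized wrapper)
.dist_polyline <- function(px, py, poly) .project_polyline(px, py, poly)$dist

# Dominant direction (unit vector) of a polyline: end minus start.
.polyline_axis <- function(poly) {
  v <- poly[nrow(poly), ] - poly[1, ]
  n <- sqrt(sum(v^2))
  if (n == 0) .stop_invalid("centerline", "zero-length polyline")
  v / n
}

# population standard deviation
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# md5 of an arbitrary R object via its canonical YAML rendering
.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f), add = TRUE)
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}
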