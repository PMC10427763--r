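# AChR/BTX scoring, cluster shape, perinuclear regions, spot counting

test_that("the modal histogram bin locates the background intensity", {
  means <- c(rep(100, 10), rep(300, 3))
  bg <- btx_background(means)
  expect_lt(abs(bg - 100), (300 - 100) / 64 + 1e-9)
  expect_warning(b2 <- btx_background(rep(50, 12)), "identical")
  expect_equal(b2, 50)
  expect_error(btx_background(c(1, 2, 3)), "pool")
})

test_that("a bimodal sample matches an exhaustive histogram oracle", {
  set.seed(11)
  means <- c(rnorm(160, 100, 5), rnorm(40, 400, 5))
  bg <- btx_background(means, 64)
  breaks <- seq(min(means), max(means), length.out = 65)
  counts <- vapply(seq_len(64), function(i)
    sum(means >= breaks[i] & (means < breaks[i + 1] | i == 64)), integer(1))
  i <- which.max(counts)
  expect_equal(bg, (breaks[i] + breaks[i + 1]) / 2)
  expect_lt(abs(bg - 100), diff(breaks)[1] + 5)
})

test_that("high-BTX classification is strict at twice background", {
  rec <- data.frame(nucleus_id = 1:10,
                    mean_btx = c(rep(100, 6), rep(300, 4)))
  cls <- classify_high_btx(rec, background = 100)
  expect_equal(cls$proportion, 0.4)
  boundary <- data.frame(mean_btx = c(200, 200.0001, 199.9999))
  cb <- classify_high_btx(boundary, background = 100)
  expect_equal(cb$records$is_high, c(FALSE, TRUE, FALSE))
  none <- classify_high_btx(data.frame(mean_btx = c(10, 20)), background = 100)
  expect_equal(none$proportion, 0)
})

test_that("classification is invariant to joint intensity rescaling", {
  set.seed(4)
  rec <- data.frame(mean_btx = runif(50, 50, 400))
  p1 <- classify_high_btx(rec, 100)$proportion
  rec2 <- rec; rec2$mean_btx <- rec2$mean_btx * 7.3
  p2 <- classify_high_btx(rec2, 730)$proportion
  expect_equal(p1, p2)
})

test_that("generator scenes round-trip the planted high-BTX proportion", {
  scn <- scene_spec(
    image_size = c(120L, 500L), pixel_size = 0.5,
    tubes = list(list(centerline = cbind(c(15, 235), c(30, 30)), width = 24)),
    nuclei = data.frame(x = seq(20, 230, length.out = 10), y = 30, radius = 3,
                        tube = 1L,
                        btx_high = rep(c(TRUE, FALSE), c(4, 6))),
    noise_sd = 2)
  gm <- generate_morphology_image(scn, 9)
  lab <- label_components(gm$channels$dapi > 60)
  rec <- nucleus_mean_intensity(gm$channels$btx, lab)
  bg <- btx_background(rec$mean_btx)
  expect_equal(classify_high_btx(rec, bg)$proportion, 0.4)
})

test_that("disk and rectangle shape metrics match analytic moments", {
  d <- disk_mask(60, 20)
  cs <- cluster_shape(d, 1)
  expect_gte(cs$circularity, 0.85); expect_lte(cs$circularity, 1.0)
  expect_gte(cs$roundness, 0.9); expect_lte(cs$roundness, 1.0)
  r <- matrix(FALSE, 30, 60); r[11:20, 11:50] <- TRUE
  cr <- cluster_shape(r, 1)
  major_analytic <- 4 * sqrt(40^2 / 12)  # continuous rectangle moments
  expect_equal(cr$major_axis_um, major_analytic, tolerance = 1e-6)
  expect_equal(cr$roundness, 4 * 400 / (pi * major_analytic^2),
               tolerance = 1e-6)
  expect_equal(cr$area_um2, 400)
})

test_that("degenerate and multi-component cluster inputs are handled", {
  p <- matrix(FALSE, 9, 9); p[5, 5] <- TRUE
  cs <- cluster_shape(p, 0.5)
  expect_equal(cs$area_um2, 0.25)
  expect_false(cs$reliable)
  two <- matrix(FALSE, 20, 20); two[2:4, 2:4] <- TRUE; two[12:14, 12:14] <- TRUE
  expect_error(cluster_shape(two, 1), "several components")
})

test_that("perinuclear bands have the analytic area and truncate at tube ends", {
  px <- 0.5
  scn <- morphology_scene(noise_sd = 0)
  gm <- generate_morphology_image(scn, 1)
  act <- gm$channels$actinin > 50
  cl <- scn$tubes[[1]]$centerline
  # mid-tube nucleus: band 100 um x 20 um width
  reg <- perinuclear_region(c(100, 50), cl, act, px, 50)
  expect_lt(abs(sum(reg) * px^2 - 100 * 20) / (100 * 20), 0.05)
  # nucleus 10 um from the tube start: band truncated to 60 um of tube run
  # (plus the rounded end cap, which projects to arc position 0)
  regt <- perinuclear_region(c(25, 50), cl, act, px, 50)
  cols <- range(which(colSums(regt) > 0))
  extent_um <- diff(cols) * px
  expect_lt(abs(extent_um - (60 + 10)), 1.5)  # 60 um run + 10 um cap
  expect_lt(sum(regt), sum(reg))
  # half-length 0 degenerates and is flagged
  reg0 <- perinuclear_region(c(100, 50), cl, act, px, 0)
  expect_true(attr(reg0, "degenerate"))
  expect_error(perinuclear_region(c(100, 180), cl, act, px, 50), "centerline")
})

test_that("planted puncta are counted exactly inside the band", {
  px <- 0.5
  scn <- morphology_scene(noise_sd = 0)
  gm <- generate_morphology_image(scn, 1)
  act <- gm$channels$actinin > 50
  fish <- gm$channels$fish > 50
  reg <- perinuclear_region(c(100, 50), scn$tubes[[1]]$centerline, act, px, 50)
  cs <- count_spots(fish, reg, normalizer_um2 = sum(reg) * px^2)
  expect_equal(cs$spot_count, 25)
  expect_equal(cs$density_per_um2, 25 / (sum(reg) * px^2))
  empty <- count_spots(matrix(FALSE, nrow(reg), ncol(reg)), reg)
  expect_equal(empty$spot_count, 0)
})

test_that("boundary straddlers count once by the centroid rule", {
  fish <- matrix(FALSE, 40, 40)
  fish[19:22, 18:23] <- TRUE          # one punctum straddling the region edge
  region <- matrix(FALSE, 40, 40); region[, 1:20] <- TRUE
  expect_equal(count_spots(fish, region)$spot_count, 1)
  region2 <- matrix(FALSE, 40, 40); region2[, 1:17] <- TRUE
  expect_equal(count_spots(fish, region2)$spot_count, 0)
})

test_that("spot counts are additive over disjoint regions", {
  set.seed(21)
  fish <- matrix(FALSE, 60, 120)
  xs <- seq(5, 115, by = 10); ys <- rep(c(15, 45), length.out = length(xs))
  for (i in seq_along(xs)) fish[ys[i] + (-1:1), xs[i] + (-1:1)] <- TRUE
  left <- matrix(FALSE, 60, 120); left[, 1:60] <- TRUE
  right <- !left
  whole <- matrix(TRUE, 60, 120)
  expect_equal(count_spots(fish, left)$spot_count +
                 count_spots(fish, right)$spot_count,
               count_spots(fish, whole)$spot_count)
})

test_that("size filters exclude out-of-range components", {
  fish <- matrix(FALSE, 30, 30)
  fish[5, 5] <- TRUE                      # area 1
  fish[10:12, 10:12] <- TRUE              # area 9
  fish[20:27, 20:27] <- TRUE              # area 64
  all3 <- count_spots(fish, matrix(TRUE, 30, 30))
  expect_equal(all3$spot_count, 3)
  mid <- count_spots(fish, matrix(TRUE, 30, 30), min_area_px = 2,
                     max_area_px = 20)
  expect_equal(mid$spot_count, 1)
})
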