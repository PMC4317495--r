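test_that("peripheral boxes tile the boundary by arc length", {
  boxes <- peripheral_boxes(square_cell(40))
  expect_length(boxes, 32)                       # perimeter 160 / 5
  expect_false(any(vapply(boxes, function(b) b$short, logical(1))))
  coverage <- sum(vapply(boxes, function(b) diff(b$arc), numeric(1)))
  expect_equal(coverage, attr(boxes, "perimeter"))
  # a box on a straight run is an exact 5 x 2 rectangle
  mid <- boxes[[2]]$polygon
  expect_equal(sort(dist(mid))[1:4], c(2, 2, 5, 5), tolerance = 1e-9)
  # non-multiple perimeter flags a final short box
  boxes2 <- peripheral_boxes(square_cell(10.5))
  expect_true(boxes2[[length(boxes2)]]$short)
  expect_error(peripheral_boxes(cbind(c(0, 1, 1), c(0, 0, 1)),
                                length_um = 50), "shorter")
  expect_error(peripheral_boxes(cbind(c(0, 1), c(0, 0))), "degenerate")
})

test_that("microtubule box counts use inclusive polygon intersection", {
  boxes <- peripheral_boxes(square_cell(40))
  # a vertical segment crossing the bottom edge at x = 2.5: box 1 only
  mts <- list(rbind(c(2.5, -1), c(2.5, 1.5)))
  bc <- mt_box_counts(mts, boxes)
  expect_equal(bc$counts[1], 1L)
  expect_equal(sum(bc$counts), 1L)
  # a segment along the shared border of boxes 1 and 2 counts in both
  border <- list(rbind(c(5, 0.5), c(5, 1.5)))
  bc2 <- mt_box_counts(border, boxes)
  expect_equal(bc2$counts[1:2], c(1L, 1L))
  expect_equal(bc2$mean, 2 / 32)
})

test_that("box counts match a brute-force intersection enumeration", {
  set.seed(8)
  boxes <- peripheral_boxes(square_cell(30))
  mts <- lapply(1:12, function(i) {
    start <- runif(2, 2, 28)
    rbind(start, start + runif(2, -6, 6))
  })
  bc <- mt_box_counts(mts, boxes)
  manual <- vapply(boxes, function(b) {
    sum(vapply(mts, function(line) {
      # oracle: dense sampling of the segment against the box polygon
      tt <- seq(0, 1, length.out = 400)
      pts <- cbind(line[1, 1] + tt * (line[2, 1] - line[1, 1]),
                   line[1, 2] + tt * (line[2, 2] - line[1, 2]))
      any(apply(pts, 1, function(p) point_in_polygon(p, b$polygon)))
    }, logical(1)))
  }, numeric(1))
  expect_equal(bc$counts, as.integer(manual))
})

test_that("tip-to-edge distances follow polygon geometry", {
  sq10 <- square_cell(10)
  expect_equal(tip_edge_distance(matrix(c(5, 5), 1), sq10), 5)  # centre
  expect_equal(tip_edge_distance(matrix(c(0, 0), 1), sq10), 0)  # vertex
  expect_error(tip_edge_distance(matrix(c(15, 5), 1), sq10), "outside")
  expect_equal(tip_edge_distance(matrix(c(15, 5), 1), sq10, strict = FALSE),
               -5)
})

test_that("distances match the per-edge oracle on random tracks in a triangle", {
  tri <- cbind(c(0, 12, 6), c(0, 0, 10))
  set.seed(10)
  pts <- matrix(NA_real_, 20, 2)
  n_found <- 0
  while (n_found < 20) {
    p <- c(runif(1, 0, 12), runif(1, 0, 10))
    if (point_in_polygon(p, tri)) {
      n_found <- n_found + 1
      pts[n_found, ] <- p
    }
  }
  d <- tip_edge_distance(pts, tri)
  want <- apply(pts, 1, oracle_edge_distance, poly = tri)
  expect_equal(d, want, tolerance = 1e-12)
})

test_that("distances are invariant under rigid motion", {
  tri <- cbind(c(0, 12, 6), c(0, 0, 10))
  set.seed(11)
  pts <- cbind(runif(5, 3, 6), runif(5, 2, 4))
  theta <- 0.7; shift <- c(13, -4)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(tip_edge_distance(pts %*% t(rot) + rep(shift, each = 5),
                                 tri %*% t(rot) + rep(shift, each = 3)),
               tip_edge_distance(pts, tri), tolerance = 1e-9)
})

test_that("membrane residence is the longest uninterrupted episode", {
  expect_equal(membrane_residence(c(5, 1.5, 1.5, 1.5, 5))$lifetime_s, 30)
  expect_equal(membrane_residence(c(5, 5, 5))$lifetime_s, 0)
  expect_equal(membrane_residence(rep(1, 7))$lifetime_s, 70)
  # interrupted episodes do not accumulate
  expect_equal(membrane_residence(c(1, 1, 5, 1, 1, 1))$lifetime_s, 30)
  expect_error(membrane_residence(numeric()), "empty")
  # monotone non-decreasing in the band width, bounded by track length
  set.seed(12)
  d <- runif(30, 0, 6)
  lifes <- vapply(c(1, 2, 4), function(b)
    membrane_residence(d, band_um = b)$lifetime_s, numeric(1))
  expect_true(all(diff(lifes) >= 0))
  expect_true(all(lifes <= 30 * 10))
})

test_that("displacement summaries separate moving from stationary tracks", {
  still <- data.frame(mt_id = "m1", frame = 0:5, x_um = 1, y_um = 1)
  run <- data.frame(mt_id = "m2", frame = 0:5, x_um = seq(0, 5), y_um = 0)
  ds <- displacement_stats(rbind(still, run))
  expect_equal(ds$per_track$mean_displacement_um[
    ds$per_track$mt_id == "m1"], 0)
  expect_equal(ds$per_track$mean_displacement_um[
    ds$per_track$mt_id == "m2"], 1)
  expect_equal(ds$per_track$n_excursions[ds$per_track$mt_id == "m1"], 0)
  expect_error(displacement_stats(still[1, , drop = FALSE]), "fewer than 2")
})

test_that("patch quantification flattens uniform fields and categorizes", {
  segs <- list(rbind(c(0, 4.5), c(25, 4.5)),
               rbind(c(4.3, 0), c(4.3, 25)),
               rbind(c(4.7, 0), c(4.7, 25)))
  pat <- sim_pattern_image(image_size = 128, pixel_size_um = 0.2,
                           mt_segments = segs, noise = 0.01, seed = 3)
  pq <- patch_quantify(pat$image, pat$layout, rolling_ball_px = 20,
                       segments = segs)
  first <- pq[pq$x_um == 4.5 & pq$y_um == 4.5, ]
  expect_equal(first$n_mts, 3)
  expect_equal(first$category, "several")
  empty <- pq[pq$x_um == 13.5 & pq$y_um == 13.5, ]
  expect_equal(empty$category, "none")
  expect_gt(first$mean_intensity, empty$mean_intensity)
  # uniform image: background subtraction removes everything
  flat <- patch_quantify(matrix(7, 128, 128), pat$layout,
                         rolling_ball_px = 20)
  expect_true(all(abs(flat$mean_intensity) <= 0.07))  # <= 1% of the level
  far <- pat$layout
  far$centres <- matrix(c(1e4, 1e4), 1)
  expect_error(patch_quantify(pat$image, far), "outside")
})

test_that("signal fraction excludes regions below the area floor", {
  mask <- matrix(FALSE, 20, 20)
  regions <- matrix(0L, 20, 20)
  regions[1:10, 1:10] <- 1L    # 100 um^2 at 1 um pixels
  mask[1:5, 1:10] <- TRUE      # half positive
  expect_equal(signal_fraction(mask, regions, pixel_size_um = 1), 50)
  # a 39-px region is excluded from numerator and denominator
  regions[15:20, 15:20] <- 2L
  regions[20, 20] <- 0L        # 35 px < 40
  mask[15:20, 15:20] <- TRUE
  expect_equal(signal_fraction(mask, regions, pixel_size_um = 1), 50)
  expect_equal(signal_fraction(regions == 1, regions * (regions == 1)), 100)
  expect_error(signal_fraction(mask, regions * 0L), "no region")
})
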