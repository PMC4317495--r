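# Quantification of microtubule cortical targeting: peripheral box
# densities, micropattern patch intensities, tip-to-edge distances,
# cortical residence lifetimes, displacement summaries and positive-signal
# area fractions.

# arc-length machinery over a closed polygon --------------------------------

.polygon_arcs <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  seg <- poly[nxt, , drop = FALSE] - poly
  len <- sqrt(rowSums(seg^2))
  list(n = n, nxt = nxt, len = len, cum = c(0, cumsum(len)),
       # inward normals per edge (polygon is CCW)
       normal = cbind(-seg[, 2], seg[, 1]) / len)
}

.point_at_arc <- function(s, poly, arcs) {
  i <- findInterval(s, arcs$cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), arcs$n)
  f <- (s - arcs$cum[i]) / arcs$len[i]
  poly[i, ] + f * (poly[arcs$nxt[i], ] - poly[i, ])
}

# inward normal at arc position s; bisector at vertices so adjacent boxes
# share their corner points
.normal_at_arc <- function(s, arcs, eps = 1e-9) {
  at_vertex <- which(abs(arcs$cum - s) < eps)
  if (length(at_vertex)) {
    v <- at_vertex[1]
    i_after <- if (v > arcs$n) 1L else v
    i_before <- if (v == 1L || v == arcs$n + 1L) arcs$n else v - 1L
    nrm <- arcs$normal[i_after, ] + arcs$normal[i_before, ]
    l <- sqrt(sum(nrm^2))
    if (l < eps) return(arcs$normal[i_after, ])
    return(nrm / l)
  }
  i <- findInterval(s, arcs$cum, rightmost.closed = TRUE)
  arcs$normal[min(max(i, 1L), arcs$n), ]
}

#' Peripheral quantification boxes around a cell
#'
#' Tiles the cell boundary by arc length into consecutive boxes, each
#' spanning `length_um` along the edge and extending `depth_um` inward
#' along the local normal (an inward-offset strip split every
#' `length_um`). The final box is shorter when the perimeter is not a
#' multiple of `length_um` and is flagged. Corners are handled with
#' bisector normals so adjacent boxes share their corner points.
#'
#' @param boundary simple closed polygon (n x 2 matrix, micrometres).
#' @param length_um box length along the periphery (default 5).
#' @param depth_um box depth toward the cell interior (default 2).
#' @return list of boxes, each a list with `polygon` (quadrilateral or
#'   corner-straddling polygon), `arc` (start, end arc positions) and
#'   `short` (logical). The attribute `perimeter` carries the total
#'   boundary length.
#' @export
peripheral_boxes <- function(boundary, length_um = 5, depth_um = 2) {
  poly <- ensure_ccw(as.matrix(boundary))
  arcs <- .polygon_arcs(poly)
  perim <- arcs$cum[arcs$n + 1]
  if (perim < length_um)
    .fail("perimeter (", round(perim, 2), " um) shorter than one box")
  starts <- seq(0, perim - 1e-9, by = length_um)
  boxes <- lapply(starts, function(s0) {
    s1 <- min(s0 + length_um, perim)
    inner_vertices <- arcs$cum[arcs$cum > s0 + 1e-9 & arcs$cum < s1 - 1e-9]
    ss <- c(s0, inner_vertices, s1)
    outer <- t(vapply(ss, .point_at_arc, numeric(2), poly = poly, arcs = arcs))
    nrml <- t(vapply(ss, .normal_at_arc, numeric(2), arcs = arcs))
    inner <- outer + depth_um * nrml
    list(polygon = rbind(outer, inner[rev(seq_len(nrow(inner))), ,
                                      drop = FALSE]),
         arc = c(s0, s1),
         short = (s1 - s0) < length_um - 1e-9)
  })
  attr(boxes, "perimeter") <- perim
  boxes
}

#' Microtubule counts per peripheral box
#'
#' A microtubule increments a box's count when its polyline intersects the
#' box polygon (boundary-inclusive); one microtubule may count in several
#' boxes but at most once per box.
#'
#' @param mts list of polylines (m x 2 matrices) in the same coordinate
#'   frame as the boxes.
#' @param boxes box list from [peripheral_boxes()].
#' @return list with `counts` (integer per box), `mean` and `sd` across
#'   boxes.
#' @export
mt_box_counts <- function(mts, boxes) {
  counts <- vapply(boxes, function(b) {
    sum(vapply(mts, function(line)
      polyline_intersects_polygon(as.matrix(line), b$polygon), logical(1)))
  }, numeric(1))
  list(counts = as.integer(counts),
       mean = mean(counts), sd = stats::sd(counts))
}

#' Quantify ligand-coated micropattern patches
#'
#' Subtracts the image background (grayscale opening with a disc
#' structuring element of the given radius - the standard rolling-ball
#' equivalent), then reports the mean background-subtracted intensity
#' within each patch disc. When ground-truth microtubule segments are
#' supplied (synthetic mode), each patch is categorized by the number of
#' microtubules whose polylines enter the disc: 0 = `"none"`,
#' 1-2 = `"1-2"`, 3 or more = `"several"`.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param layout patch layout: list with `centres` (k x 2, micrometres),
#'   `diameter_um` and `pixel_size_um` (see [sim_pattern_image()]).
#' @param mask optional logical matrix selecting measurable patches: a
#'   patch is kept when the mask is TRUE at its centre pixel.
#' @param rolling_ball_px structuring-element radius in pixels
#'   (default 50); 0 skips background subtraction.
#' @param segments optional list of microtubule polylines (micrometres)
#'   used for the categorization.
#' @return data.frame with x_um, y_um, mean_intensity, n_mts, category.
#' @export
patch_quantify <- function(image, layout, mask = NULL,
                           rolling_ball_px = 50, segments = NULL) {
  px <- layout$pixel_size_um
  r_um <- layout$diameter_um / 2
  if (rolling_ball_px > 0) {
    brush <- EBImage::makeBrush(2 * rolling_ball_px + 1, shape = "disc")
    # EBImage grayscale morphology saturates outside [0, 1]: rescale,
    # open, and map the background-subtracted result back
    rng <- range(image)
    span <- rng[2] - rng[1]
    if (span > 0) {
      scaled <- (image - rng[1]) / span
      image <- (scaled - EBImage::opening(scaled, brush)) * span
    } else {
      image <- image * 0  # constant field: background equals the image
    }
  }
  ny <- nrow(image); nx <- ncol(image)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  rows <- lapply(seq_len(nrow(layout$centres)), function(i) {
    cx <- layout$centres[i, 1]; cy <- layout$centres[i, 2]
    if (cx + r_um < 0 || cy + r_um < 0 ||
        cx - r_um > nx * px || cy - r_um > ny * px)
      .fail("patch ", i, " lies fully outside the image")
    if (!is.null(mask)) {
      ci <- min(max(1L, round(cy / px + 0.5)), ny)
      cj <- min(max(1L, round(cx / px + 0.5)), nx)
      if (!mask[ci, cj]) return(NULL)
    }
    inx <- which(abs(xs - cx) <= r_um)
    iny <- which(abs(ys - cy) <= r_um)
    sub <- expand.grid(i = iny, j = inx)
    d2 <- (xs[sub$j] - cx)^2 + (ys[sub$i] - cy)^2
    sel <- sub[d2 <= r_um^2, , drop = FALSE]
    mi <- mean(image[cbind(sel$i, sel$j)])
    n_mts <- if (is.null(segments)) NA_integer_ else {
      sum(vapply(segments, function(line) {
        line <- as.matrix(line)
        m <- nrow(line)
        any(dist_point_segment(cx, cy,
                               line[-m, 1], line[-m, 2],
                               line[-1, 1], line[-1, 2]) <= r_um)
      }, logical(1)))
    }
    category <- if (is.na(n_mts)) NA_character_
      else if (n_mts == 0) "none" else if (n_mts <= 2) "1-2" else "several"
    data.frame(x_um = cx, y_um = cy, mean_intensity = mi,
               n_mts = n_mts, category = category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance from microtubule tips to the cell edge
#'
#' Per frame, the Euclidean distance from the tip position to the nearest
#' point of the cell-boundary polygon; zero on the boundary.
#'
#' @param track data.frame with `x_um`, `y_um` (one row per frame) or an
#'   m x 2 matrix of tip positions.
#' @param boundary cell-boundary polygon (n x 2 matrix).
#' @param strict when TRUE (default) a tip outside the boundary is an
#'   error; when FALSE it is reported with a negative sign.
#' @return numeric distance series (micrometres).
#' @export
tip_edge_distance <- function(track, boundary, strict = TRUE) {
  pts <- if (is.data.frame(track)) cbind(track$x_um, track$y_um)
         else as.matrix(track)
  boundary <- as.matrix(boundary)
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    d <- polygon_edge_distance(p, boundary)
    if (!point_in_polygon(p, boundary)) {
      if (strict) .fail("tip at frame ", i, " lies outside the boundary")
      return(-d)
    }
    d
  }, numeric(1))
}

#' Cortical residence lifetime of a microtubule
#'
#' The length of time a microtubule remains within `band_um` of the cell
#' periphery: the longest run of consecutive frames with tip-to-edge
#' distance at most the band, times the frame interval. A single
#' uninterrupted episode, not cumulative time.
#'
#' @param series distance series from [tip_edge_distance()].
#' @param band_um cortical band width (default 2).
#' @param dt_s frame interval in seconds (default 10).
#' @param breaks optional numeric breaks (seconds) for a binned class
#'   label, passed to [cut()] with `include.lowest = TRUE,
#'   right = FALSE`.
#' @return list with `lifetime_s`, `run_frames`, and `class` (factor or
#'   NA when no breaks given).
#' @export
membrane_residence <- function(series, band_um = 2, dt_s = 10,
                               breaks = NULL) {
  if (!length(series)) .fail("empty distance series")
  inband <- series <= band_um
  runs <- rle(inband)
  run_frames <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  lifetime <- run_frames * dt_s
  cls <- if (is.null(breaks)) NA else
    cut(lifetime, breaks = breaks, include.lowest = TRUE, right = FALSE)
  list(lifetime_s = lifetime, run_frames = as.integer(run_frames),
       class = cls)
}

#' Residence lifetimes for a whole track set
#'
#' Applies [tip_edge_distance()] and [membrane_residence()] to every
#' microtubule of a simulated or imported track set.
#'
#' @param track_set list with `tracks` (mt_id, frame, x_um, y_um),
#'   `boundary` and `frame_interval_s` (see [sim_tracks()]).
#' @param band_um cortical band width (default 2).
#' @return data.frame with mt_id, lifetime_s, run_frames.
#' @export
residence_lifetimes <- function(track_set, band_um = 2) {
  dt <- track_set$frame_interval_s
  rows <- lapply(split(track_set$tracks, track_set$tracks$mt_id),
                 function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    d <- tip_edge_distance(tr, track_set$boundary)
    res <- membrane_residence(d, band_um = band_um, dt_s = dt)
    data.frame(mt_id = tr$mt_id[1], lifetime_s = res$lifetime_s,
               run_frames = res$run_frames, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Displacement and growth-excursion summaries of tip tracks
#'
#' Frame-to-frame tip displacements per track, with growth excursions
#' defined as maximal runs of frames whose displacement exceeds the pause
#' threshold (shrinkage and pause events are thereby excluded from the
#' excursion speed distribution).
#'
#' @param track_set track set (see [sim_tracks()]) or a data.frame with
#'   mt_id, frame, x_um, y_um.
#' @param pause_threshold_um displacement below which a frame counts as
#'   paused (default 0.1 um/frame).
#' @return list with `per_track` (mt_id, mean_displacement_um,
#'   n_excursions, mean_excursion_speed_um) and `excursion_speeds`
#'   (um/frame, pooled over tracks).
#' @export
displacement_stats <- function(track_set, pause_threshold_um = 0.1) {
  tracks <- if (is.data.frame(track_set)) track_set else track_set$tracks
  speeds_all <- numeric()
  rows <- lapply(split(tracks, tracks$mt_id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) .fail("track ", tr$mt_id[1], " has fewer than 2 frames")
    disp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    runs <- rle(disp > pause_threshold_um)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    exc <- which(runs$values)
    speeds <- vapply(exc, function(e) mean(disp[starts[e]:ends[e]]),
                     numeric(1))
    speeds_all <<- c(speeds_all, speeds)
    data.frame(mt_id = tr$mt_id[1],
               mean_displacement_um = mean(disp),
               n_excursions = length(exc),
               mean_excursion_speed_um = if (length(speeds)) mean(speeds)
                                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_track <- do.call(rbind, rows)
  rownames(per_track) <- NULL
  list(per_track = per_track, excursion_speeds = speeds_all)
}

#' Positive-signal fraction over size-filtered regions
#'
#' Measured regions smaller than `min_area_um2` are excluded from both
#' numerator and denominator; the result is the percentage of positive
#' pixels among all pixels of the retained regions.
#'
#' @param mask logical matrix of positive signal.
#' @param regions integer label matrix of the same dimensions (0 =
#'   unmeasured).
#' @param min_area_um2 minimum region area (default 40).
#' @param pixel_size_um physical pixel size (default 1).
#' @return percentage in [0, 100].
#' @export
signal_fraction <- function(mask, regions, min_area_um2 = 40,
                            pixel_size_um = 1) {
  if (!all(dim(mask) == dim(regions)))
    .fail("mask and region images differ in size")
  labs <- setdiff(unique(as.vector(regions)), 0)
  areas <- vapply(labs, function(l)
    sum(regions == l) * pixel_size_um^2, numeric(1))
  keep <- labs[areas >= min_area_um2]
  if (!length(keep)) .fail("no region reaches ", min_area_um2, " um^2")
  sel <- regions %in% keep
  100 * sum(mask[sel]) / sum(sel)
}
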