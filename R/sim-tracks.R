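#' Configuration for the microtubule tip-track simulator
#'
#' Two-state dynamics: each microtubule grows from an interior nucleation
#' point toward the cell edge; once its tip enters the cortical band it
#' dwells there for a geometric number of frames (mean
#' `cortical_dwell_frames`), then undergoes catastrophe and re-nucleates at
#' an interior point under the same id. A stimulatory cortical environment
#' is emulated by a larger mean dwell than an inhibitory one.
#'
#' @param boundary simple closed polygon (n x 2 matrix, micrometres).
#' @param n_microtubules number of tracked microtubules.
#' @param n_frames frames per track.
#' @param frame_interval_s acquisition interval in seconds (default 10).
#' @param growth_speed_um_per_frame tip advance per frame during growth.
#' @param catastrophe_prob per-frame catastrophe probability during growth.
#' @param cortical_dwell_frames mean dwell (frames) in the cortical band.
#' @param cortical_band_um width of the cortical band (default 2).
#' @param regime label stored with the output (`"stimulatory"` or
#'   `"inhibitory"`); purely descriptive - the dynamics are set by
#'   `cortical_dwell_frames`.
#' @param seed integer RNG seed.
#' @return list of class `sim_track_config`.
#' @export
sim_track_config <- function(boundary,
                             n_microtubules = 50L,
                             n_frames = 60L,
                             frame_interval_s = 10,
                             growth_speed_um_per_frame = 2,
                             catastrophe_prob = 0.02,
                             cortical_dwell_frames = 4,
                             cortical_band_um = 2,
                             regime = c("stimulatory", "inhibitory"),
                             seed = 1L) {
  regime <- match.arg(regime)
  boundary <- as.matrix(boundary)
  if (!is_simple_polygon(boundary))
    .fail("boundary polygon is not simple (self-intersecting)")
  .assert_scalar_number(frame_interval_s, "frame_interval_s", positive = TRUE)
  .assert_scalar_number(growth_speed_um_per_frame,
                        "growth_speed_um_per_frame", positive = TRUE)
  if (cortical_dwell_frames < 1)
    .fail("'cortical_dwell_frames' must be at least 1 frame")
  structure(list(boundary = ensure_ccw(boundary),
                 n_microtubules = as.integer(n_microtubules),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 growth_speed_um_per_frame = growth_speed_um_per_frame,
                 catastrophe_prob = catastrophe_prob,
                 cortical_dwell_frames = cortical_dwell_frames,
                 cortical_band_um = cortical_band_um,
                 regime = regime,
                 seed = as.integer(seed)),
            class = "sim_track_config")
}

#' Simulate microtubule tip trajectories
#'
#' @param config a [sim_track_config()].
#' @return list with `tracks` (data.frame: mt_id, frame, t_s, x_um, y_um),
#'   `boundary`, `frame_interval_s` and `regime`. All tip positions lie
#'   inside or on the boundary; frames are uniformly spaced.
#' @export
sim_tracks <- function(config) {
  stopifnot(inherits(config, "sim_track_config"))
  set.seed(config$seed)
  poly <- config$boundary
  band <- config$cortical_band_um
  speed <- config$growth_speed_um_per_frame
  p_dwell_exit <- 1 / config$cortical_dwell_frames

  nucleate <- function() {
    p <- random_interior_point(poly, margin = band)
    ang <- stats::runif(1, 0, 2 * pi)
    list(pos = p, dir = c(cos(ang), sin(ang)), state = "growth")
  }

  n_mt <- config$n_microtubules
  nf <- config$n_frames
  out <- vector("list", n_mt)
  for (m in seq_len(n_mt)) {
    st <- nucleate()
    xs <- numeric(nf); ys <- numeric(nf)
    for (f in seq_len(nf)) {
      xs[f] <- st$pos[1]; ys[f] <- st$pos[2]
      if (st$state == "growth") {
        if (stats::runif(1) < config$catastrophe_prob) {
          st <- nucleate()
          next
        }
        target <- st$pos + speed * st$dir
        thit <- segment_boundary_hit(st$pos, target, poly)
        if (is.finite(thit) && thit <= 1) {
          # clamp just inside the edge and switch to cortical dwell
          st$pos <- st$pos + 0.999 * thit * speed * st$dir
          st$state <- "dwell"
        } else {
          st$pos <- target
          if (polygon_edge_distance(st$pos, poly) <= band) st$state <- "dwell"
        }
      } else {  # dwelling at the cortex
        if (stats::runif(1) < p_dwell_exit) st <- nucleate()
      }
    }
    out[[m]] <- data.frame(mt_id = sprintf("MT%04d", m),
                           frame = seq_len(nf) - 1L,
                           t_s = (seq_len(nf) - 1L) * config$frame_interval_s,
                           x_um = xs, y_um = ys,
                           stringsAsFactors = FALSE)
  }
  list(tracks = do.call(rbind, out),
       boundary = poly,
       frame_interval_s = config$frame_interval_s,
       regime = config$regime)
}

#' Simulate a micropatterned-substrate image
#'
#' Renders microtubule polylines as bright Gaussian-profile ridges over
#' additive Gaussian background noise, and returns the ligand-patch layout:
#' discs of `patch_diameter_um` arranged on a square lattice at
#' `pitch_um` centre-to-centre spacing.
#'
#' @param patch_diameter_um patch diameter (default 2).
#' @param pitch_um lattice pitch between patch centres (default 9).
#' @param image_size image side length in pixels (square image).
#' @param pixel_size_um physical pixel size.
#' @param mt_segments list of polylines (m x 2 matrices, micrometres) to
#'   render; may be empty.
#' @param ridge_sigma_um Gaussian ridge width (default 0.2).
#' @param noise standard deviation of additive Gaussian background noise.
#' @param seed integer RNG seed.
#' @return list with `image` (numeric matrix, rows = y) and `layout`
#'   (list: `centres` k x 2 matrix, `diameter_um`, `pitch_um`,
#'   `pixel_size_um`).
#' @export
sim_pattern_image <- function(patch_diameter_um = 2, pitch_um = 9,
                              image_size = 256, pixel_size_um = 0.2,
                              mt_segments = list(), ridge_sigma_um = 0.2,
                              noise = 0, seed = 1L) {
  if (pitch_um <= patch_diameter_um)
    .fail("'pitch_um' must exceed 'patch_diameter_um'")
  if (patch_diameter_um / pixel_size_um < 2)
    .fail("pixel size too coarse to resolve a ", patch_diameter_um,
          " um patch (< 2 px across)")
  set.seed(seed)
  img <- matrix(0, image_size, image_size)
  if (noise > 0)
    img <- img + matrix(stats::rnorm(image_size^2, sd = noise),
                        image_size, image_size)
  # pixel-centre coordinates in micrometres
  px <- (seq_len(image_size) - 0.5) * pixel_size_um
  if (length(mt_segments)) {
    xg <- matrix(px, image_size, image_size, byrow = TRUE)   # column = x
    yg <- matrix(px, image_size, image_size)                 # row = y
    for (line in mt_segments) {
      line <- as.matrix(line)
      for (i in seq_len(nrow(line) - 1)) {
        d <- dist_point_segment(as.vector(xg), as.vector(yg),
                                line[i, 1], line[i, 2],
                                line[i + 1, 1], line[i + 1, 2])
        img <- img + matrix(exp(-d^2 / (2 * ridge_sigma_um^2)),
                            image_size, image_size)
      }
    }
  }
  extent <- image_size * pixel_size_um
  cent1 <- seq(pitch_um / 2, extent - patch_diameter_um / 2, by = pitch_um)
  centres <- as.matrix(expand.grid(x_um = cent1, y_um = cent1))
  list(image = img,
       layout = list(centres = centres,
                     diameter_um = patch_diameter_um,
                     pitch_um = pitch_um,
                     pixel_size_um = pixel_size_um))
}
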