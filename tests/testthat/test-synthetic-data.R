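test_that("count simulator is seed-deterministic and respects its invariants", {
  cfg <- sim_count_config(200, baseline_mean = 20,
                          frac_active_enriched = 0.1,
                          frac_unique_active = 0.05, seed = 11)
  a <- sim_counts(cfg)
  b <- sim_counts(cfg)
  expect_identical(a, b)
  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_equal(unname(a$design$total_spectra),
               unname(pmax(colSums(a$counts), 1L)))
  expect_equal(ncol(a$counts), 2 * 2 * 2)  # 2 conditions x 2 bio x 2 tech
  expect_setequal(unique(a$truth$class),
                  c("active_enriched", "unique_active", "null"))
})

test_that("invalid count configurations are rejected", {
  expect_error(sim_count_config(100, frac_active_enriched = 0.6,
                                frac_inactive_enriched = 0.6),
               "sum to more than 1")
  expect_error(sim_count_config(100, planted_fold = 1), "exceed 1")
  expect_error(sim_count_config(100, baseline_mean = -2), "positive")
})

test_that("null simulation gives a balanced condition ratio", {
  cfg <- sim_count_config(3000, baseline_mean = 20, seed = 4)
  sim <- sim_counts(cfg)
  act <- sim$design$sample_id[sim$design$condition == "active"]
  ina <- sim$design$sample_id[sim$design$condition == "inactive"]
  ratio <- mean(sim$counts[, act]) / mean(sim$counts[, ina])
  expect_equal(ratio, 1, tolerance = 0.02)
})

test_that("realized fold enrichment of the planted class matches the target", {
  folds <- vapply(1:20, function(s) {
    cfg <- sim_count_config(2000, baseline_mean = 50, planted_fold = 4,
                            frac_active_enriched = 0.1, seed = s)
    sim <- sim_counts(cfg)
    nsc <- compute_nsc(sim$counts, sim$design, sim$meta)
    agg <- aggregate_replicates(nsc, sim$design)
    q <- fold_enrichment(agg$condition_mean)
    planted <- sim$truth$accession[sim$truth$class == "active_enriched"]
    stats::median(q$fold[q$accession %in% planted], na.rm = TRUE)
  }, numeric(1))
  expect_true(median(folds) >= 3 && median(folds) <= 5)
})

test_that("interactome generator produces simple graphs with the seed node", {
  g <- sim_interactome(5, 10, seed_node = "ITGB1", seed = 1)
  expect_equal(igraph::ecount(g), 10)  # complete graph on 5 nodes
  expect_equal(sum(igraph::which_loop(g)), 0)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_true(all(adj[upper.tri(adj)] == 1))
  expect_true("ITGB1" %in% igraph::V(g)$name)
  expect_error(sim_interactome(5, 11), "exceeds the maximum")
  # determinism
  expect_identical(igraph::as_edgelist(sim_interactome(50, 100, seed = 3)),
                   igraph::as_edgelist(sim_interactome(50, 100, seed = 3)))
})

test_that("scale-free model has a heavier degree tail than Erdos-Renyi", {
  heavier <- vapply(1:20, function(s) {
    sf <- sim_interactome(500, 1500, model = "scale-free", seed = s)
    er <- sim_interactome(500, 1500, model = "erdos-renyi", seed = s)
    max(igraph::degree(sf)) > max(igraph::degree(er))
  }, logical(1))
  expect_gte(mean(heavier), 0.90)
})

test_that("annotation generator respects sizes, purity and planting", {
  bg <- sprintf("G%04d", 1:600)
  truth <- data.frame(accession = bg,
                      class = rep(c("active_enriched", "null"), c(60, 540)))
  ann <- sim_annotations(25, bg, truth, size_range = c(5, 80),
                         planted = list(list(term = "PL", class =
                           "active_enriched", purity = 1, size = 20)),
                         seed = 2)
  expect_true(all(lengths(ann) >= 5 & lengths(ann) <= 80))
  expect_true(all(ann$PL %in% truth$accession[truth$class ==
                                                "active_enriched"]))
  expect_identical(ann, sim_annotations(25, bg, truth,
                   size_range = c(5, 80),
                   planted = list(list(term = "PL", class =
                     "active_enriched", purity = 1, size = 20)), seed = 2))
  expect_error(sim_annotations(5, bg[1:50], size_range = c(5, 100)),
               "background smaller")
})

test_that("planted terms dominate random terms in Fisher significance", {
  bg <- sprintf("G%04d", 1:300)
  truth <- data.frame(accession = bg,
                      class = rep(c("active_enriched", "null"), c(40, 260)))
  query <- truth$accession[truth$class == "active_enriched"]
  wins <- vapply(1:100, function(s) {
    ann <- sim_annotations(1, bg, truth, size_range = c(15, 25),
                           planted = list(list(term = "PL", class =
                             "active_enriched", purity = 0.9, size = 20)),
                           seed = s)
    p <- vapply(ann, function(members) {
      k <- length(intersect(members, query))
      oracle_hyper_tail(k, length(members), length(bg), length(query))
    }, numeric(1))
    p["PL"] < p[names(p) != "PL"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("track simulator keeps tips in bounds on a uniform time base", {
  cfg <- sim_track_config(square_cell(30), n_microtubules = 20,
                          n_frames = 40, seed = 5)
  ts <- sim_tracks(cfg)
  expect_identical(ts$tracks, sim_tracks(cfg)$tracks)
  inside <- vapply(seq_len(nrow(ts$tracks)), function(i)
    point_in_polygon(c(ts$tracks$x_um[i], ts$tracks$y_um[i]), ts$boundary),
    logical(1))
  expect_true(all(inside))
  one <- ts$tracks[ts$tracks$mt_id == "MT0001", ]
  expect_equal(one$t_s, seq(0, by = 10, length.out = 40))
  bow_tie <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))
  expect_error(sim_track_config(bow_tie), "not simple")
})

test_that("cortical band occupancy rises with the planted dwell", {
  frac_in_band <- function(dwell, s) {
    cfg <- sim_track_config(square_cell(30), n_microtubules = 30,
                            n_frames = 40, cortical_dwell_frames = dwell,
                            seed = s)
    ts <- sim_tracks(cfg)
    d <- vapply(seq_len(nrow(ts$tracks)), function(i)
      polygon_edge_distance(c(ts$tracks$x_um[i], ts$tracks$y_um[i]),
                            ts$boundary), numeric(1))
    mean(d <= 2)
  }
  ok <- vapply(1:20, function(s) {
    f <- vapply(c(2, 6, 12), frac_in_band, numeric(1), s = s)
    all(diff(f) > 0)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("pattern image layout has the prescribed lattice and clean empty case", {
  pat <- sim_pattern_image(image_size = 128, pixel_size_um = 0.2,
                           noise = 0, seed = 1)
  expect_true(all(pat$image == 0))
  cx <- sort(unique(pat$layout$centres[, 1]))
  expect_equal(unique(diff(cx)), 9)       # 9 um centre-to-centre pitch
  expect_equal(pat$layout$diameter_um, 2) # 2 um patches
  expect_error(sim_pattern_image(pixel_size_um = 1.5), "too coarse")
})
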