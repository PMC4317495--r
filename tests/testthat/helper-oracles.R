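# Independent reference implementations used to check the package's fast
# paths. These deliberately share no code with the implementation: plain
# loops, choose()-sum enumeration, and boolean matrix powers.

# uncentred Pearson by explicit summation
oracle_uncentred_r <- function(x, y) {
  sx <- 0; sy <- 0; sxy <- 0
  for (i in seq_along(x)) {
    sx <- sx + x[i]^2; sy <- sy + y[i]^2; sxy <- sxy + x[i] * y[i]
  }
  if (sx == 0 || sy == 0) return(0)
  sxy / sqrt(sx * sy)
}

# naive agglomerative complete-linkage clustering under d = 1 - r.
# Returns merge heights (sorted) and the partition obtained by merging
# every pair of clusters whose complete-linkage distance is <= 1 - r_min.
oracle_complete_linkage <- function(m, r_min = 0.80) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- 1 - oracle_uncentred_r(m[i, ], m[j, ])
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  cl_dist <- function(a, b) max(d[a, b])
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- cl_dist(clusters[[a]], clusters[[b]])
      if (dd < best[1]) best <- c(dd, a, b)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-best[3]]
  }
  # partition: redo the agglomeration, stopping at the threshold
  clusters <- lapply(seq_len(n), identity)
  repeat {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- cl_dist(clusters[[a]], clusters[[b]])
      if (dd < best[1]) best <- c(dd, a, b)
    }
    if (!is.finite(best[1]) || best[1] > 1 - r_min + 1e-9) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-best[3]]
    if (length(clusters) == 1) break
  }
  list(heights = sort(heights),
       partition = lapply(clusters, sort))
}

# canonical form of a partition (list of index/name sets) for comparison
canonical_partition <- function(p) {
  p <- unname(lapply(p, function(s) sort(as.character(s))))
  p[order(vapply(p, `[`, character(1), 1))]
}

# hypergeometric upper tail P(X >= k) by choose()-sum enumeration
oracle_hyper_tail <- function(k, K, N, n) {
  js <- seq(max(0, k), min(K, n))
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hop distances by boolean adjacency-matrix powers
oracle_hops <- function(adj, seed_idx) {
  n <- nrow(adj)
  hops <- rep(NA_integer_, n)
  hops[seed_idx] <- 0L
  reach <- diag(n)
  for (k in seq_len(n)) {
    reach <- (reach %*% adj) > 0
    newly <- which(reach[seed_idx, ] & is.na(hops))
    hops[newly] <- k
    if (!anyNA(hops)) break
  }
  hops
}

# point-to-polygon distance by an explicit per-edge loop
oracle_edge_distance <- function(p, poly) {
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(1, max(0, t))
    q <- a + t * ab
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

# a small square cell boundary used across cortical tests
square_cell <- function(side = 40) {
  cbind(c(0, side, side, 0), c(0, 0, side, side))
}

# run the quantification + clustering pipeline on one simulated data set
run_cluster_pipeline <- function(cfg) {
  sim <- sim_counts(cfg)
  keep <- filter_min_count(sim$counts)
  nsc <- compute_nsc(sim$counts[keep, , drop = FALSE], sim$design, sim$meta)
  agg <- aggregate_replicates(nsc, sim$design)
  quant <- fold_enrichment(agg$condition_mean)
  clusters <- extract_clusters(hclust_profiles(profile_matrix(agg$bio)),
                               r_min = 0.80)
  assignment <- label_clusters(clusters, quant)
  list(sim = sim, quant = quant, assignment = assignment)
}
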