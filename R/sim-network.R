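#' Simulate a protein interaction network
#'
#' Generates an undirected simple graph with exactly `n_edges` edges and a
#' designated seed node (the bait integrin in downstream hop analysis).
#' The scale-free model draws edges with power-law (Zipf) fitness weights,
#' which produces the heavy-tailed degree distributions of real
#' interactomes while holding the edge count exact; the Erdos-Renyi model
#' is the uniform G(n, m) reference.
#'
#' @param n_nodes number of proteins.
#' @param n_edges number of interactions; must not exceed
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @param seed_node identifier given to the designated seed protein.
#' @param model `"scale-free"` or `"erdos-renyi"`.
#' @param seed integer RNG seed.
#' @return an [igraph][igraph::igraph-package] graph with vertex names and a
#'   `seed` graph attribute naming the seed node.
#' @export
sim_interactome <- function(n_nodes, n_edges, seed_node = "ITGB1",
                            model = c("scale-free", "erdos-renyi"),
                            seed = 1L) {
  model <- match.arg(model)
  n_nodes <- as.integer(n_nodes)
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    .fail("n_edges exceeds the maximum for a simple graph on ",
          n_nodes, " nodes")
  set.seed(seed)
  g <- if (model == "scale-free") {
    igraph::sample_fitness(n_edges, fitness.out = seq_len(n_nodes)^(-1),
                           loops = FALSE, multiple = FALSE)
  } else {
    igraph::sample_gnm(n_nodes, n_edges)
  }
  nms <- sprintf("P%04d", seq_len(n_nodes))
  nms[1] <- seed_node  # highest-fitness node doubles as the bait hub
  igraph::V(g)$name <- nms
  g$seed <- seed_node
  g
}

#' Simulate a gene-set annotation collection
#'
#' Draws `n_terms` random terms over the background, with sizes uniform in
#' `size_range`, and optionally plants terms whose members are drawn
#' preferentially from one truth class (fraction `purity` from the class,
#' the rest at random), mirroring how genuinely coherent functional terms
#' concentrate condition-specific proteins.
#'
#' @param n_terms number of random (non-planted) terms.
#' @param background character vector of protein identifiers.
#' @param truth optional data.frame (accession, class) from [sim_counts()];
#'   required when `planted` is given.
#' @param size_range inclusive (min, max) term size; terms outside 5-500
#'   would be discarded downstream, so the default mirrors that window.
#' @param planted optional list of lists with fields `term`, `class`,
#'   `purity` (fraction of members from the class) and `size`.
#' @param seed integer RNG seed.
#' @return named list of character vectors (term id -> member proteins).
#' @export
sim_annotations <- function(n_terms, background, truth = NULL,
                            size_range = c(5, 500), planted = NULL,
                            seed = 1L) {
  if (size_range[1] < 1 || size_range[1] > size_range[2])
    .fail("invalid size_range")
  if (size_range[2] > length(background))
    .fail("background smaller than the maximum term size")
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(background, k))
  names(sets) <- sprintf("T%04d", seq_len(n_terms))
  for (p in planted) {
    if (is.null(truth)) .fail("planted terms require truth labels")
    pool <- truth$accession[truth$class == p$class]
    k_cls <- round(p$size * p$purity)
    if (k_cls > length(pool))
      .fail("truth class '", p$class, "' smaller than purity * size")
    members <- sample(pool, k_cls)
    rest <- setdiff(background, members)
    if (p$size > k_cls)
      members <- c(members, sample(rest, p$size - k_cls))
    sets[[p$term]] <- members
  }
  sets
}
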