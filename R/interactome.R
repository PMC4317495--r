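#' Build a merged protein-protein interaction graph
#'
#' Unions one or more edge lists into a single undirected simple graph:
#' duplicate edges and reversals are collapsed, self-interactions dropped,
#' and the source list(s) of every edge recorded as provenance. The seed
#' protein (the bait integrin for hop analysis) is added as an isolated
#' node when absent.
#'
#' @param edge_lists named list of two-column character matrices (or a
#'   single matrix); names become provenance labels.
#' @param seed_node identifier of the seed protein (default `"ITGB1"`).
#' @param mapping optional two-column data.frame (from, to) applied to all
#'   identifiers before merging.
#' @return an igraph graph with vertex names, edge attribute `sources`
#'   (comma-collapsed provenance) and graph attribute `seed`.
#' @export
build_interactome <- function(edge_lists, seed_node = "ITGB1",
                              mapping = NULL) {
  if (is.matrix(edge_lists) || is.data.frame(edge_lists))
    edge_lists <- list(edges = edge_lists)
  if (is.null(names(edge_lists)))
    names(edge_lists) <- paste0("source", seq_along(edge_lists))
  remap <- function(x) {
    if (is.null(mapping)) return(x)
    i <- match(x, mapping[[1]])
    ifelse(is.na(i), x, mapping[[2]][i])
  }
  rows <- lapply(names(edge_lists), function(src) {
    e <- as.matrix(edge_lists[[src]])
    if (!nrow(e)) return(NULL)
    a <- remap(as.character(e[, 1])); b <- remap(as.character(e[, 2]))
    keep <- a != b  # self-interactions excluded
    if (!any(keep)) return(NULL)
    data.frame(from = pmin(a, b)[keep], to = pmax(a, b)[keep],
               source = src, stringsAsFactors = FALSE)
  })
  ed <- do.call(rbind, rows)
  if (is.null(ed) || nrow(ed) == 0) .fail("no edges after merging")
  key <- paste(ed$from, ed$to)
  prov <- vapply(split(ed$source, key), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))
  uniq <- ed[!duplicated(key), c("from", "to")]
  uniq$sources <- prov[paste(uniq$from, uniq$to)]
  g <- igraph::graph_from_data_frame(uniq, directed = FALSE)
  if (!seed_node %in% igraph::V(g)$name)
    g <- igraph::add_vertices(g, 1, name = seed_node)
  g$seed <- seed_node
  g
}

#' Hop distances from the seed protein
#'
#' Breadth-first shortest-path hop counts from the graph's seed node.
#' Unreachable proteins are reported as `NA` ("not connected").
#'
#' @param graph igraph graph from [build_interactome()] (or any graph with
#'   a `seed` attribute).
#' @param nodes vertex names to report (default all).
#' @return data.frame with protein, hop (integer or NA).
#' @export
hop_distances <- function(graph, nodes = igraph::V(graph)$name) {
  seed <- graph$seed
  if (is.null(seed) || !seed %in% igraph::V(graph)$name)
    .fail("graph has no valid seed node")
  d <- igraph::distances(graph, v = seed, to = nodes)[1, ]
  hop <- rep(NA_integer_, length(d))
  hop[is.finite(d)] <- as.integer(d[is.finite(d)])
  data.frame(protein = nodes, hop = hop,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Functional-class summary of the identified adhesome
#'
#' For each adhesome functional class: how many components the class
#' roster lists, how many were identified by MS, the integer percentage
#' identified, and the median log2 fold change of the identified members
#' (NA when none identified).
#'
#' @param roster data.frame with `accession` and `functional_class` for
#'   every adhesome component.
#' @param identified character vector of identified proteins.
#' @param quant data.frame with `accession` and `log2fc`.
#' @return data.frame with functional_class, n_in_adhesome, n_identified,
#'   pct_identified, median_log2fc.
#' @export
class_summary <- function(roster, identified, quant) {
  lfc <- stats::setNames(quant$log2fc, quant$accession)
  out <- lapply(split(roster$accession, roster$functional_class),
                function(acc) {
    idf <- intersect(acc, identified)
    data.frame(n_in_adhesome = length(acc),
               n_identified = length(idf),
               pct_identified = round_half_up(100 * length(idf) / length(acc)),
               median_log2fc = if (length(idf))
                 stats::median(lfc[idf], na.rm = TRUE) else NA_real_)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(functional_class = rownames(res),
                          stringsAsFactors = FALSE), res)
  rownames(res) <- NULL
  res
}

#' Intersection of network neighbourhoods
#'
#' Nodes within `radius` hops of at least one member of each of two
#' protein sets, excluding the sets themselves - the screen used to
#' nominate candidates linking two interaction neighbourhoods.
#'
#' @param graph igraph graph.
#' @param set_a,set_b character vectors of vertex names.
#' @param radius neighbourhood radius in hops (>= 1, default 1).
#' @return character vector of candidate vertex names (sorted).
#' @export
neighborhood_intersection <- function(graph, set_a, set_b, radius = 1) {
  if (radius < 1) .fail("'radius' must be at least 1")
  # ego() returns vertex sequences; collect their names
  nbrs <- function(s) {
    s <- intersect(s, igraph::V(graph)$name)
    if (!length(s)) return(character())
    unique(unlist(lapply(igraph::ego(graph, order = radius, nodes = s),
                         function(v) v$name)))
  }
  cand <- intersect(nbrs(set_a), nbrs(set_b))
  sort(setdiff(cand, union(set_a, set_b)))
}
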