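#' Uncentred Pearson correlation
#'
#' Cosine-type similarity without mean-centring:
#' `r = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`. Defined as 0 when either
#' vector is all-zero (no similarity evidence), which keeps clustering
#' total over sparse profiles.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1].
#' @export
uncentred_pearson <- function(x, y) {
  if (length(x) != length(y)) .fail("vectors differ in length")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) return(0)
  r <- sum(x * y) / sqrt(sx * sy)
  max(-1, min(1, r))
}

#' Pairwise uncentred Pearson similarity of matrix rows
#'
#' @param m numeric matrix (rows = profiles).
#' @return symmetric similarity matrix with unit diagonal (0 diagonal for
#'   all-zero rows).
#' @export
uncentred_cor_rows <- function(m) {
  norms <- sqrt(rowSums(m^2))
  s <- tcrossprod(m)
  denom <- outer(norms, norms)
  r <- ifelse(denom > 0, s / denom, 0)
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

#' Feature matrix for profile clustering
#'
#' Builds the clustering input from the per-biological-replicate summed
#' NSC columns. The default keeps NSC on its natural scale: uncentred
#' Pearson correlation compares profile *directions*, and on raw NSC a
#' protein enriched fourfold in one state points in a clearly different
#' direction from an unenriched one. A log2 transform (offered as an
#' option) adds a large common offset to every column, which drives all
#' pairwise uncentred correlations toward 1 and collapses the cluster
#' structure; when requested, zeros are floored at half the smallest
#' positive NSC so the transform stays finite.
#'
#' @param bio proteins x replicate-column NSC matrix
#'   (from [aggregate_replicates()]`$bio`).
#' @param transform `"none"` (default) or `"log2"`.
#' @param floor optional explicit additive floor for the log transform.
#' @return numeric matrix of clustering profiles.
#' @export
profile_matrix <- function(bio, transform = c("none", "log2"),
                           floor = NULL) {
  transform <- match.arg(transform)
  if (transform == "none") return(bio)
  if (is.null(floor)) {
    pos <- bio[bio > 0]
    floor <- if (length(pos)) min(pos) / 2 else 1
  }
  log2(bio + floor)
}

#' Complete-linkage hierarchical clustering of profiles
#'
#' Agglomerative clustering under distance `d = 1 - r` with `r` the
#' uncentred Pearson correlation between row profiles, merged with
#' complete linkage. Node similarity is `1 - height` at each merge.
#'
#' @param m numeric matrix with at least 2 rows; all entries finite.
#' @return an `hclust` object (labels = rownames).
#' @export
hclust_profiles <- function(m) {
  if (nrow(m) < 2) .fail("need at least 2 rows to cluster")
  if (any(!is.finite(m))) .fail("non-finite entries in profile matrix")
  d <- stats::as.dist(1 - uncentred_cor_rows(m))
  stats::hclust(d, method = "complete")
}

#' Extract clusters at a correlation threshold
#'
#' Cuts the tree at distance `1 - r_min`: the clusters are the maximal
#' subtrees all of whose merge similarities are at least `r_min`
#' (singletons allowed). Implemented by union-find over the merge list so
#' merges at exactly the threshold are included.
#'
#' @param tree `hclust` object from [hclust_profiles()].
#' @param r_min minimum node similarity (default 0.80); in (-1, 1].
#' @return named list of character vectors (cluster id -> accessions),
#'   ordered by decreasing size.
#' @export
extract_clusters <- function(tree, r_min = 0.80) {
  if (r_min <= -1 || r_min > 1) .fail("'r_min' must lie in (-1, 1]")
  n <- length(tree$labels)
  h_max <- 1 - r_min + 1e-9
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cluster_of_merge <- integer(nrow(tree$merge))  # leaf representative
  for (k in seq_len(nrow(tree$merge))) {
    mem <- vapply(tree$merge[k, ], function(j)
      if (j < 0) -j else cluster_of_merge[j], integer(1))
    cluster_of_merge[k] <- mem[1]
    if (tree$height[k] <= h_max) {
      r1 <- find(mem[1]); r2 <- find(mem[2])
      parent[r2] <- r1
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(tree$labels, roots)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- sprintf("C%03d", seq_along(groups))
  groups
}

#' Label clusters by enrichment direction
#'
#' A cluster is labelled `active` when the median log2 fold change of its
#' members exceeds `+neutral_band`, `inactive` below `-neutral_band`, and
#' `unenriched` within the band. The default band of 0.58 log2 units is a
#' 1.5-fold enrichment, the overrepresentation threshold used elsewhere in
#' the pipeline.
#'
#' @param clusters list of accession vectors (from [extract_clusters()]).
#' @param quant data.frame with `accession` and `log2fc`
#'   (from [fold_enrichment()]).
#' @param neutral_band half-width of the unenriched band in log2 units.
#' @return data.frame with accession, cluster_id, label.
#' @export
label_clusters <- function(clusters, quant, neutral_band = 0.58) {
  if (any(lengths(clusters) == 0)) .fail("empty cluster")
  lfc <- stats::setNames(quant$log2fc, quant$accession)
  out <- lapply(names(clusters), function(cid) {
    acc <- clusters[[cid]]
    if (anyNA(lfc[acc]))
      .fail("log2fc missing for clustered protein(s): ",
            paste(acc[is.na(lfc[acc])], collapse = ", "))
    med <- stats::median(lfc[acc])
    lab <- if (med > neutral_band) "active"
           else if (med < -neutral_band) "inactive"
           else "unenriched"
    data.frame(accession = acc, cluster_id = cid, label = lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Adhesome coverage statistics
#'
#' Compares the identified proteins and their cluster labels with a
#' literature-curated adhesome inventory (core vs associated components).
#'
#' @param assignment data.frame from [label_clusters()] (accession,
#'   cluster_id, label).
#' @param identified character vector of all identified proteins.
#' @param inventory data.frame with `accession` and `division`
#'   (`"core"` / `"associated"`).
#' @return list with n_inventory, n_identified, pct_identified,
#'   n_state_specific, pct_state_specific (of identified adhesome members
#'   labelled active or inactive), and core_pct_by_label (named integer
#'   percentages of core components per label).
#' @export
adhesome_coverage <- function(assignment, identified, inventory) {
  if (is.null(inventory) || nrow(inventory) == 0)
    .fail("empty adhesome inventory")
  inv <- unique(inventory$accession)
  id_adh <- intersect(unique(identified), inv)
  lab <- stats::setNames(assignment$label, assignment$accession)
  labs <- lab[id_adh]
  state_specific <- id_adh[!is.na(labs) & labs %in% c("active", "inactive")]
  division <- stats::setNames(inventory$division, inventory$accession)
  core_pct <- sapply(c("active", "inactive", "unenriched"), function(l) {
    members <- id_adh[!is.na(labs) & labs == l]
    if (!length(members)) return(NA_real_)
    round_half_up(100 * mean(division[members] == "core"))
  })
  list(n_inventory = length(inv),
       n_identified = length(id_adh),
       pct_identified = round_half_up(100 * length(id_adh) / length(inv)),
       n_state_specific = length(state_specific),
       pct_state_specific = if (length(id_adh) == 0) 0 else
         round_half_up(100 * length(state_specific) / length(id_adh)),
       core_pct_by_label = core_pct)
}
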