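#' Overrepresentation test for a term collection
#'
#' For each term, tests whether the query protein list is enriched for the
#' term's members relative to the background: `p_fisher` is the
#' hypergeometric upper tail P(X >= k) (one-sided Fisher's exact test) and
#' `p_ease` is the conservative EASE score - the same tail with the
#' observed overlap reduced by one (an overlap of 0 or 1 scores p = 1).
#' Bonferroni correction is applied over the number of terms tested.
#'
#' @param query character vector; must be a subset of `background`.
#' @param background character vector (the testing universe).
#' @param terms named list of character vectors; members outside the
#'   background are ignored.
#' @return data.frame with term, k (overlap), n (query size), K (term size
#'   in background), N (background size), fold_enrichment, p_fisher,
#'   p_ease, p_bonferroni.
#' @export
ora_test <- function(query, background, terms) {
  background <- unique(background)
  query <- unique(query)
  stray <- setdiff(query, background)
  if (length(stray))
    .fail("query protein(s) absent from background: ",
          paste(utils::head(stray, 10), collapse = ", "))
  N <- length(background)
  if (N < 2) .fail("background must contain at least 2 proteins")
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(terms[[tm]], background)
    K <- length(members)
    k <- length(intersect(members, query))
    pf <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    pe <- if (k <= 1) 1 else
      stats::phyper(k - 2, K, N - K, n, lower.tail = FALSE)
    fe <- if (n > 0 && K > 0) (k / n) / (K / N) else 0
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               fold_enrichment = fe, p_fisher = pf, p_ease = pe,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p_fisher * nrow(res))
  rownames(res) <- NULL
  res
}

#' Filter overrepresented terms (keyword-style criteria)
#'
#' A term passes when all four conditions hold: fold enrichment at least
#' `fe_min` (boundary passes), Bonferroni-corrected P strictly below
#' `p_bonf_max`, EASE score strictly below `ease_max`, and at least
#' `k_min` query proteins carrying the term.
#'
#' @param results data.frame from [ora_test()].
#' @param fe_min minimum fold enrichment (default 1.5, inclusive).
#' @param p_bonf_max Bonferroni P cut (default 0.05, exclusive).
#' @param ease_max EASE score cut (default 0.05, exclusive).
#' @param k_min minimum overlap (default 2).
#' @return the input with a logical `passes` column added.
#' @export
filter_overrepresented <- function(results, fe_min = 1.5,
                                   p_bonf_max = 0.05, ease_max = 0.05,
                                   k_min = 2) {
  results$passes <- results$fold_enrichment >= fe_min &
    results$p_bonferroni < p_bonf_max &
    results$p_ease < ease_max &
    results$k >= k_min
  results
}

#' Randomization false discovery rate for overrepresented terms
#'
#' For each of `n_rand` randomizations a uniform random query of the same
#' size is drawn from the background and all term Fisher p values are
#' recomputed. The FDR of a term with observed p is the mean number of
#' random-term p values at or below it, divided by the number of observed
#' term p values at or below it, capped at 1 - the expected over observed
#' discovery count at that threshold.
#'
#' @param query,background,terms as in [ora_test()].
#' @param n_rand number of randomizations (default 100).
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @return data.frame from [ora_test()] with an `fdr` column added.
#' @export
permutation_fdr <- function(query, background, terms, n_rand = 100,
                            seed = 1L) {
  if (n_rand < 1) .fail("'n_rand' must be at least 1")
  obs <- ora_test(query, background, terms)
  set.seed(seed)
  background <- unique(background)
  n <- length(unique(query))
  rand_p <- replicate(n_rand, {
    rq <- sample(background, n)
    ora_test(rq, background, terms)$p_fisher
  })
  rand_p <- matrix(rand_p, ncol = n_rand)
  obs$fdr <- vapply(obs$p_fisher, function(p) {
    expected <- mean(colSums(rand_p <= p))
    observed <- sum(obs$p_fisher <= p)
    min(1, expected / observed)
  }, numeric(1))
  obs
}

#' Build a fold-change-annotated enrichment map
#'
#' Constructs the matrix of overrepresented terms x proteins filled with
#' each annotated protein's log2 fold change (NA where the protein is not
#' annotated to the term), restricted to terms with between `size_min` and
#' `size_max` assigned identified proteins. Term rows are clustered with
#' uncentred Pearson correlation and complete linkage; missing entries are
#' imputed as 0 (no enrichment evidence) for the distance computation only.
#'
#' @param results data.frame from [ora_test()] /
#'   [filter_overrepresented()]; only rows with `passes == TRUE` are used
#'   when a `passes` column exists.
#' @param terms named list of term memberships.
#' @param quant data.frame with `accession` and `log2fc`; proteins without
#'   a log2fc are not part of the map.
#' @param size_min,size_max inclusive bounds on assigned-protein count
#'   (defaults 5 and 500).
#' @return list with `matrix` (terms x proteins, NA = unannotated),
#'   `term_tree` (`hclust` over terms, NULL when < 2 terms), and
#'   `term_stats` (term, n_assigned, median_log2fc, neg_log10_p).
#' @export
build_enrichment_map <- function(results, terms, quant,
                                 size_min = 5, size_max = 500) {
  if ("passes" %in% names(results))
    results <- results[results$passes, , drop = FALSE]
  lfc <- stats::setNames(quant$log2fc, quant$accession)
  lfc <- lfc[!is.na(lfc)]
  keep <- character()
  assigned <- list()
  for (tm in results$term) {
    members <- intersect(terms[[tm]], names(lfc))
    if (length(members) >= size_min && length(members) <= size_max) {
      keep <- c(keep, tm)
      assigned[[tm]] <- members
    }
  }
  if (!length(keep))
    return(list(matrix = matrix(numeric(), 0, 0), term_tree = NULL,
                term_stats = data.frame()))
  proteins <- sort(unique(unlist(assigned)))
  m <- matrix(NA_real_, length(keep), length(proteins),
              dimnames = list(keep, proteins))
  for (tm in keep) m[tm, assigned[[tm]]] <- lfc[assigned[[tm]]]
  p_of <- stats::setNames(results$p_fisher, results$term)
  stats_df <- data.frame(
    term = keep,
    n_assigned = lengths(assigned)[keep],
    median_log2fc = apply(m, 1, stats::median, na.rm = TRUE),
    neg_log10_p = -log10(pmax(p_of[keep], .Machine$double.xmin)),
    row.names = NULL, stringsAsFactors = FALSE)
  tree <- if (length(keep) >= 2) {
    imputed <- m
    imputed[is.na(imputed)] <- 0
    hclust_profiles(imputed)
  } else NULL
  list(matrix = m, term_tree = tree, term_stats = stats_df)
}
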