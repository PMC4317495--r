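#' Read a spectral-count matrix from TSV
#'
#' The file holds one row per protein, one column per sample; the first
#' column carries protein accessions and becomes the rownames.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix, proteins x samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) .fail("negative spectral counts in ", path)
  m
}

#' Write a spectral-count matrix to TSV
#'
#' @param counts integer matrix, proteins x samples (rownames = accessions).
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(accession = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Expected columns: `sample_id`, `condition` (\"active\"/\"inactive\"),
#' `bio_rep`, `tech_rep`, `total_spectra`.
#'
#' @param path path to a tab-separated file.
#' @return data.frame.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(df)
  df
}

validate_design <- function(design) {
  need <- c("sample_id", "condition", "bio_rep", "tech_rep", "total_spectra")
  miss <- setdiff(need, names(design))
  if (length(miss)) .fail("design table lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (any(design$total_spectra <= 0))
    .fail("total_spectra must be positive for every sample")
  key <- paste(design$condition, design$bio_rep, design$tech_rep)
  if (anyDuplicated(key))
    .fail("duplicate (condition, bio_rep, tech_rep) combination in design")
  invisible(design)
}

#' Read a protein metadata table from TSV
#'
#' Expected columns: `accession`, `symbol`, `mw_kda`, `adhesome`
#' (\"core\"/\"associated\"/\"none\"), `functional_class`, `is_tip`.
#'
#' @param path path to a tab-separated file.
#' @return data.frame.
#' @export
read_meta_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "mw_kda") %in% names(df)))
    .fail("metadata table needs at least 'accession' and 'mw_kda'")
  if (any(df$mw_kda <= 0)) .fail("molecular weights must be positive")
  df
}

#' Read a SIF ('A pp B') or two-column edge list
#'
#' SIF lines are `node1<ws>relation<ws>node2`; two-column files are
#' `node1<ws>node2`. Whitespace-delimited; lines with other shapes error.
#'
#' @param path path to the edge-list file.
#' @return two-column character matrix of edges.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(matrix(character(), ncol = 2))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (all(nf == 3L)) {
    edges <- t(vapply(parts, function(p) p[c(1L, 3L)], character(2)))
  } else if (all(nf == 2L)) {
    edges <- t(vapply(parts, function(p) p[1:2], character(2)))
  } else {
    .fail("edge list ", path, " mixes line formats (expected 2 or 3 fields)")
  }
  edges
}

#' Write an edge list in SIF format
#'
#' @param edges two-column character matrix.
#' @param path output path.
#' @param relation interaction type written in the middle column.
#' @export
write_sif <- function(edges, path, relation = "pp") {
  writeLines(paste(edges[, 1], relation, edges[, 2]), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path path to a GMT file (term, description, members...).
#' @return named list of character vectors (term id -> member proteins).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions
#'   (defaults to the term names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read tip tracks from CSV
#'
#' Expected columns: `mt_id`, `frame`, `t_s`, `x_um`, `y_um`.
#'
#' @param path path to a CSV file.
#' @return data.frame ordered by (mt_id, frame).
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mt_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) .fail("tracks file lacks column(s): ",
                          paste(miss, collapse = ", "))
  df[order(df$mt_id, df$frame), , drop = FALSE]
}

#' Read a cell-boundary polygon from CSV
#'
#' One vertex per line, columns `x_um`, `y_um` (or two unnamed columns).
#'
#' @param path path to a CSV file.
#' @return two-column numeric matrix of vertices.
#' @export
read_boundary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, 1:2])
  colnames(m) <- c("x_um", "y_um")
  m
}

#' Write a cluster tree as Newick
#'
#' Leaf names are protein accessions (or term ids) and branch lengths
#' derive from the merge distances, via [ape::as.phylo()].
#'
#' @param tree an `hclust` object.
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
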