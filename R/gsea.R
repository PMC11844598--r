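# Probe x category binary incidence, hierarchical clustering, and
# hypergeometric over-representation of gene sets.

#' Binary probe-by-category incidence matrix
#'
#' Cell (probe, category) is 1 when the probe is reported in at least `t`
#' papers of that category; rows are restricted to probes passing the
#' threshold in at least one category, so every row has at least one 1.
#'
#' @param incidences Named list of `category_incidence` tibbles (one per
#'   top-level category).
#' @param t Reporting threshold (default 2).
#' @return Integer 0/1 matrix, rows = probe IDs (sorted), columns =
#'   category names.
#' @export
build_binary_matrix <- function(incidences, t = 2) {
  if (length(incidences) < 1) abort("need at least one category incidence")
  passing <- lapply(incidences, filter_min_papers, t = t)
  probes <- sort(unique(unlist(passing, use.names = FALSE)))
  mat <- vapply(passing, function(ids) as.integer(probes %in% ids),
                integer(length(probes)))
  if (length(probes) == 1) mat <- matrix(mat, nrow = 1, dimnames = list(probes, names(incidences)))
  else rownames(mat) <- probes
  mat
}

#' Hierarchical clustering of binary incidence rows
#'
#' Jaccard distance (via [vegan::vegdist()]) with average linkage.
#' Rows are sorted by name before clustering, so the result is invariant
#' to input row order.
#'
#' @param mat Binary matrix from [build_binary_matrix()] (>= 2 rows).
#' @param metric Distance metric passed to `vegdist` (default
#'   `"jaccard"` on presence/absence).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `order` (row names in dendrogram order) and `tree`
#'   (the `hclust` object).
#' @export
cluster_rows <- function(mat, metric = "jaccard", linkage = "average") {
  if (nrow(mat) < 2) {
    return(list(order = rownames(mat), tree = NULL))
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  d <- vegan::vegdist(mat, method = metric, binary = TRUE)
  tree <- stats::hclust(d, method = linkage)
  list(order = rownames(mat)[tree$order], tree = tree)
}

#' Map probes to gene symbols
#'
#' @param probes Character vector of probe IDs.
#' @param annotation Tibble (probe_id, gene).
#' @return Character vector of unique gene symbols; unmapped probes are
#'   dropped with an informative message.
#' @export
probe_to_genes <- function(probes, annotation) {
  probes <- unique(probes)
  hit <- annotation |> dplyr::filter(.data$probe_id %in% probes)
  n_unmapped <- length(setdiff(probes, hit$probe_id))
  if (n_unmapped > 0) {
    inform(sprintf("%d probe(s) had no gene annotation and were dropped", n_unmapped))
  }
  sort(unique(hit$gene))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing at least the observed overlap when
#' `|query|` genes are sampled from the universe; Benjamini-Hochberg
#' adjustment across all tested sets. Sets are intersected with the
#' universe first; the query must be a subset of the universe.
#'
#' @param query Character vector of query genes.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of background genes (nonempty).
#' @return An `ora_result` tibble (set_name, overlap, set_size,
#'   query_size, universe_size, p, p_adj), sorted by `p_adj` then `p`.
#' @export
#' @examples
#' ora(letters[1:5], list(s = letters[1:5]), letters[1:20])
ora <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` is empty")
  query <- unique(query)
  if (!all(query %in% universe)) abort("`query` must be a subset of `universe`")
  N <- length(universe)
  q <- length(query)
  res <- purrr::imap_dfr(gene_sets, function(members, nm) {
    set <- intersect(unique(members), universe)
    K <- length(set)
    ov <- length(intersect(set, query))
    tibble(set_name = nm, overlap = ov, set_size = K, query_size = q,
           universe_size = N,
           p = stats::phyper(ov - 1, K, N - K, q, lower.tail = FALSE))
  })
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res <- res |> arrange(.data$p_adj, .data$p)
  class(res) <- c("ora_result", class(res))
  res
}

#' @rdname ora
#' @param x An `ora_result`.
#' @param ... Unused.
#' @method tidy ora_result
#' @export
tidy.ora_result <- function(x, ...) as_tibble(x)

#' @rdname ora
#' @method glance ora_result
#' @export
glance.ora_result <- function(x, ...) {
  tibble(n_sets = nrow(x), n_significant = sum(x$p_adj < 0.05),
         top_set = if (nrow(x) > 0) x$set_name[1] else NA_character_)
}
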