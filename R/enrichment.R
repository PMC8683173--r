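#' Hypergeometric over-representation analysis
#'
#' For each gene set, the overlap `k` between the query and the set within
#' the universe is scored with the hypergeometric upper tail
#' `P[X >= k]` under `Hypergeometric(N, K, n)` (exact summation via the
#' distribution function), where `N` is the universe size, `K` the set size
#' inside the universe and `n` the query size. `k = 0` yields `P = 1` (the
#' upper tail at zero carries all the mass). Results are sorted by P;
#' significance is flagged at raw `p < p_threshold` and a BH-adjusted FDR
#' column is reported alongside.
#'
#' Query genes absent from the universe are dropped with a warning.
#'
#' @param query character vector of gene ids of interest.
#' @param universe character vector, the background gene population.
#' @param gene_sets named list of gene sets as from [read_gmt()].
#' @param p_threshold raw-P significance cutoff (default 0.05).
#' @return data.frame with `set_id`, `description`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `significant`, `overlap` (semicolon-joined ids).
#' @export
ora <- function(query, universe, gene_sets, p_threshold = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  empty <- data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      significant = logical(), overlap = character())
  if (!length(query)) {
    warning("empty query after intersecting with the universe")
    return(empty)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(gene_sets, function(gs) {
    members <- intersect(unique(gs$members), universe)
    K <- length(members)
    hit <- intersect(members, query)
    k <- length(hit)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = gs$set_id, description = gs$description,
               k = k, K = K, n = n, N = N, p_value = p,
               overlap = paste(sort(hit), collapse = ";"))
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_value, "BH")
  res$significant <- res$p_value < p_threshold
  res <- res[order(res$p_value, res$set_id),
             c("set_id", "description", "k", "K", "n", "N", "p_value",
               "fdr", "significant", "overlap")]
  rownames(res) <- NULL
  res
}

#' Split differentially expressed genes by direction
#'
#' Partitions the `is_de` probes of a differential-expression table into
#' up- and downregulated gene lists (sign of `log2fc`), for
#' direction-specific enrichment. A zero log2 fold change cannot pass the
#' fold-change gate, so the partition is exhaustive.
#'
#' @param de data.frame from [moderated_t_test()].
#' @param ids optional replacement identifiers (e.g. gene symbols) aligned
#'   with `de$probe_id`; defaults to the probe ids.
#' @return list with character vectors `up` and `down`.
#' @export
split_by_direction <- function(de, ids = NULL) {
  if (is.null(ids)) ids <- de$probe_id
  stopifnot(length(ids) == nrow(de))
  sel <- de$is_de
  stopifnot(all(de$log2fc[sel] != 0))
  list(up = ids[sel & de$log2fc > 0],
       down = ids[sel & de$log2fc < 0])
}
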