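#' Two-sided P for a Pearson correlation
#'
#' Uses the exact null distribution of the product-moment correlation under
#' bivariate normality: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom. Vectorized over `r`.
#'
#' @param r correlation coefficient(s), in `[-1, 1]`.
#' @param n sample count used to compute `r` (must be >= 4).
#' @return two-sided P value(s); `|r| = 1` gives exactly 0.
#' @export
correlation_p <- function(r, n) {
  if (any(n < 4L)) stop("correlation test needs n >= 4")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(r) == 1] <- 0
  p
}

#' Build the coding-noncoding coexpression (CNC) network
#'
#' Computes the Pearson correlation between every differentially expressed
#' lncRNA and every differentially expressed mRNA across the selected
#' samples (all samples pooled by default) and keeps edges with
#' `|pcc| > pcc_threshold` and `p < p_threshold` (both strict, matching the
#' conventional `|PCC| > 0.7` wording). Probes with zero variance are
#' dropped with a warning (their correlation is undefined). Nodes without a
#' surviving edge are not part of the network.
#'
#' @param x a `cnc_expression` object.
#' @param de a moderated-test result table ([moderated_t_test()]) whose
#'   `is_de` rows define the candidate nodes.
#' @param pcc_threshold absolute-correlation cutoff, strict (default 0.7).
#' @param p_threshold correlation-test P cutoff, strict (default 0.05).
#' @param samples `"pooled"` (default) correlates across all samples;
#'   `"case"`/`"control"` restrict to one group.
#' @return object of class `cnc_network`: list with `edges` (data.frame
#'   `lnc_id`, `mrna_id`, `pcc`, `p_value`, `fdr`, `n`; `fdr` is BH over all
#'   candidate pairs), `nodes` (data.frame `id`, `biotype`, `direction`,
#'   `degree`), and the thresholds used.
#' @export
build_cnc <- function(x, de, pcc_threshold = 0.7, p_threshold = 0.05,
                      samples = c("pooled", "case", "control")) {
  stopifnot(inherits(x, "cnc_expression"))
  samples <- match.arg(samples)
  cols <- switch(samples, pooled = colnames(x$values),
                 case = case_samples(x), control = control_samples(x))
  lnc_ids <- de$probe_id[de$is_de & de$biotype == "lncRNA"]
  mrna_ids <- de$probe_id[de$is_de & de$biotype == "mRNA"]
  if (!length(lnc_ids) || !length(mrna_ids))
    stop("need a non-empty DE list for both biotypes to build a CNC network")

  lm_ <- t(x$values[lnc_ids, cols, drop = FALSE])
  mm_ <- t(x$values[mrna_ids, cols, drop = FALSE])
  zv_l <- apply(lm_, 2L, stats::sd) == 0
  zv_m <- apply(mm_, 2L, stats::sd) == 0
  if (any(zv_l) || any(zv_m)) {
    warning("dropping ", sum(zv_l) + sum(zv_m),
            " zero-variance probe(s); correlation undefined")
    lm_ <- lm_[, !zv_l, drop = FALSE]
    mm_ <- mm_[, !zv_m, drop = FALSE]
  }
  n <- length(cols)
  rmat <- stats::cor(lm_, mm_)
  pmat <- correlation_p(rmat, n)
  fdrmat <- matrix(stats::p.adjust(pmat, "BH"), nrow(pmat), ncol(pmat))
  keep <- which(abs(rmat) > pcc_threshold & pmat < p_threshold,
                arr.ind = TRUE)
  edges <- data.frame(
    lnc_id = rownames(rmat)[keep[, 1L]],
    mrna_id = colnames(rmat)[keep[, 2L]],
    pcc = rmat[keep], p_value = pmat[keep], fdr = fdrmat[keep],
    n = rep(n, nrow(keep)))
  edges <- edges[order(edges$lnc_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL

  ids <- c(unique(edges$lnc_id), unique(edges$mrna_id))
  deg <- table(factor(c(edges$lnc_id, edges$mrna_id), levels = ids))
  nodes <- data.frame(
    id = ids,
    biotype = de$biotype[match(ids, de$probe_id)],
    direction = sign(de$log2fc[match(ids, de$probe_id)]),
    degree = as.integer(deg[ids]))
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes,
                 pcc_threshold = pcc_threshold, p_threshold = p_threshold,
                 samples = samples, n = n),
            class = "cnc_network")
}

#' @export
print.cnc_network <- function(x, ...) {
  cat("cnc_network: ", nrow(x$edges), " edges over ",
      sum(x$nodes$biotype == "lncRNA"), " lncRNA and ",
      sum(x$nodes$biotype == "mRNA"), " mRNA nodes (|pcc| > ",
      x$pcc_threshold, ", p < ", x$p_threshold, ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Select hub nodes by degree centrality
#'
#' Degree centrality is the raw edge count of a node; hubs are nodes with
#' degree strictly greater than `min_degree` (the conventional network
#' cutoff is 60).
#'
#' @param network a `cnc_network`.
#' @param min_degree strict lower bound on degree (default 60).
#' @return the node table restricted to hubs, with an `is_hub` column;
#'   possibly zero rows.
#' @export
degree_filter <- function(network, min_degree = 60) {
  stopifnot(inherits(network, "cnc_network"))
  hubs <- network$nodes[network$nodes$degree > min_degree, , drop = FALSE]
  if (nrow(hubs)) hubs$is_hub <- TRUE
  else hubs$is_hub <- logical(0)
  rownames(hubs) <- NULL
  hubs
}

#' Top-ranked coexpression edges
#'
#' Edges sorted by ascending P, ties broken by larger `|pcc|`, then by
#' `(lnc_id, mrna_id)` lexicographically for a deterministic order. Returns
#' the first `k` (all edges when fewer exist).
#'
#' @param network a `cnc_network`.
#' @param k number of edges to return (default 30).
#' @return data.frame of at most `k` edges.
#' @export
top_edges <- function(network, k = 30) {
  stopifnot(inherits(network, "cnc_network"))
  if (k < 1) stop("k must be >= 1")
  e <- network$edges
  ord <- order(e$p_value, -abs(e$pcc), e$lnc_id, e$mrna_id)
  out <- e[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
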