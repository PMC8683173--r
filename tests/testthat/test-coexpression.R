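# small helper: a de-results-like table declaring every probe DE
all_de_table <- function(x) {
  lfc <- log2_fold_change(x)
  lfc$is_de <- TRUE
  lfc
}

test_that("correlation P: bounds, degenerate cases, cor.test agreement", {
  expect_equal(correlation_p(0, 22), 1)
  expect_equal(correlation_p(1, 22), 0)
  expect_equal(correlation_p(-1, 22), 0)
  expect_error(correlation_p(0.5, 3), "n >= 4")

  set.seed(301)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    xv <- rnorm(n); yv <- rnorm(n)
    ct <- cor.test(xv, yv)
    expect_equal(correlation_p(cor(xv, yv), n), ct$p.value,
                 tolerance = 1e-12)
  }
})

test_that("pcc is symmetric and affine-invariant", {
  set.seed(302)
  xv <- rnorm(22); yv <- rnorm(22)
  expect_equal(cor(xv, yv), cor(yv, xv), tolerance = 1e-12)
  expect_equal(cor(3 * xv - 7, yv), cor(xv, yv), tolerance = 1e-12)
  expect_equal(cor(xv, -2 * yv + 1), -cor(xv, yv), tolerance = 1e-12)
})

test_that("build_cnc computes product-moment correlations and strict cuts", {
  v <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 5), c(4, 3, 2, 1))
  rownames(v) <- c("L1", "M1", "M2")
  x <- tiny_expression(v, n_case = 2, biotype = c("lncRNA", "mRNA", "mRNA"))
  net <- build_cnc(x, all_de_table(x), pcc_threshold = 0.7,
                   p_threshold = 0.9)
  e <- net$edges[net$edges$mrna_id == "M1", ]
  expect_equal(e$pcc, 0.9827076, tolerance = 1e-6)

  # an exact-threshold correlation is excluded (strict >)
  net2 <- build_cnc(x, all_de_table(x),
                    pcc_threshold = abs(cor(v[1, ], v[2, ])),
                    p_threshold = 0.9)
  expect_false(any(net2$edges$mrna_id == "M1"))
})

test_that("zero-variance probes are dropped with a warning", {
  v <- rbind(rnorm(6), rep(2, 6), rnorm(6))
  rownames(v) <- c("L1", "M1", "M2")
  x <- tiny_expression(v, n_case = 3, biotype = c("lncRNA", "mRNA", "mRNA"))
  expect_warning(net <- build_cnc(x, all_de_table(x), pcc_threshold = 0,
                                  p_threshold = 1), "zero-variance")
  expect_false("M1" %in% net$edges$mrna_id)
})

test_that("network bookkeeping: bipartite, degrees, threshold monotonicity", {
  cfg <- synthetic_config(n_lnc = 40, n_mrna = 60, n_de_lnc = 0,
                          n_de_mrna = 0, n_linked_pairs = 30,
                          planted_rho = 0.85, n_cis_pairs = 0, seed = 303)
  x <- generate_expression(cfg)$expression
  de <- all_de_table(x)
  net <- build_cnc(x, de)

  # strictly bipartite; degree equals an independent edge-count pass
  expect_true(all(net$edges$lnc_id %in% de$probe_id[de$biotype == "lncRNA"]))
  expect_true(all(net$edges$mrna_id %in% de$probe_id[de$biotype == "mRNA"]))
  cnt <- table(c(net$edges$lnc_id, net$edges$mrna_id))
  expect_equal(net$nodes$degree, as.integer(cnt[net$nodes$id]),
               ignore_attr = TRUE)
  expect_false(any(duplicated(pair_key(net$edges))))

  # edge count monotone non-increasing in both thresholds
  n_loose <- nrow(build_cnc(x, de, pcc_threshold = 0.5)$edges)
  n_tight <- nrow(build_cnc(x, de, pcc_threshold = 0.9)$edges)
  expect_lte(nrow(net$edges), n_loose)
  expect_lte(n_tight, nrow(net$edges))
  n_ptight <- nrow(build_cnc(x, de, p_threshold = 1e-6)$edges)
  expect_lte(n_ptight, nrow(net$edges))

  expect_error(build_cnc(x, de[de$biotype == "mRNA", ]), "non-empty DE list")
})

test_that("hub selection uses strictly-greater raw degree", {
  star_edges <- data.frame(lnc_id = "L1", mrna_id = sprintf("M%02d", 1:61),
                           pcc = 0.9, p_value = 1e-6, fdr = 1e-5, n = 22)
  mk_net <- function(edges) {
    ids <- c(unique(edges$lnc_id), unique(edges$mrna_id))
    deg <- table(factor(c(edges$lnc_id, edges$mrna_id), levels = ids))
    structure(list(edges = edges,
                   nodes = data.frame(id = ids,
                                      biotype = ifelse(grepl("^L", ids),
                                                       "lncRNA", "mRNA"),
                                      direction = rep(1, length(ids)),
                                      degree = as.integer(deg[ids])),
                   pcc_threshold = 0.7, p_threshold = 0.05,
                   samples = "pooled", n = 22), class = "cnc_network")
  }
  expect_equal(degree_filter(mk_net(star_edges))$id, "L1")
  expect_equal(nrow(degree_filter(mk_net(star_edges[1:60, ]))), 0)
  expect_equal(nrow(degree_filter(mk_net(star_edges[0, ]))), 0)
})

test_that("top_edges ranks by P with |pcc| then lexicographic tie-breaks", {
  edges <- data.frame(
    lnc_id = c("L2", "L1", "L1", "L3"), mrna_id = c("M1", "M2", "M1", "M3"),
    pcc = c(0.8, 0.95, 0.8, 0.99), p_value = c(0.01, 0.01, 0.01, 0.001),
    fdr = 0.1, n = 22)
  net <- structure(list(edges = edges,
                        nodes = data.frame(id = character(),
                                           biotype = character(),
                                           direction = numeric(),
                                           degree = integer()),
                        pcc_threshold = 0.7, p_threshold = 0.05,
                        samples = "pooled", n = 22), class = "cnc_network")
  top <- top_edges(net, k = 30)      # fewer edges than k: all returned
  expect_equal(nrow(top), 4)
  expect_equal(pair_key(top), c("L3 M3", "L1 M2", "L1 M1", "L2 M1"))

  # independent sort oracle
  ord <- order(edges$p_value, -abs(edges$pcc), edges$lnc_id, edges$mrna_id)
  expect_equal(pair_key(top), pair_key(edges[ord, ]))

  expect_equal(nrow(top_edges(net, k = 2)), 2)
  expect_error(top_edges(net, k = 0), "k must be")
})
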