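test_that("invalid configs are rejected naming the offending field", {
  expect_error(synthetic_config(n_de_lnc = 10, n_lnc = 5), "n_de_lnc")
  expect_error(synthetic_config(n_cis_pairs = 10, n_linked_pairs = 5),
               "n_cis_pairs")
  expect_error(synthetic_config(planted_rho = 1), "planted_rho")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_lnc = -1), "n_lnc")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_lnc = 60, n_mrna = 80, n_de_lnc = 5,
                          n_de_mrna = 5, n_linked_pairs = 4,
                          n_cis_pairs = 2, seed = 11)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_annotation(cfg, a$truth),
                   generate_annotation(cfg, b$truth))
  t5 <- a$truth$de$probe_id[1:3]
  expect_identical(generate_qpcr(cfg, a$truth, t5),
                   generate_qpcr(cfg, b$truth, t5))
  # different seed changes the truth
  cfg2 <- synthetic_config(n_lnc = 60, n_mrna = 80, n_de_lnc = 5,
                           n_de_mrna = 5, n_linked_pairs = 4,
                           n_cis_pairs = 2, seed = 12)
  expect_false(identical(generate_expression(cfg2)$expression$values,
                         a$expression$values))
})

test_that("planted fold changes land where planted", {
  cfg <- synthetic_config(n_lnc = 500, n_mrna = 500, n_de_lnc = 100,
                          n_de_mrna = 100, planted_log2fc = 1.5,
                          noise_sd = 0.5, n_linked_pairs = 0,
                          n_cis_pairs = 0, seed = 21)
  g <- generate_expression(cfg)
  lfc <- log2_fold_change(g$expression)
  de <- g$truth$de
  observed <- lfc$log2fc[match(de$probe_id, lfc$probe_id)] * de$direction
  # SE of a single log2fc estimate; the mean over 200 probes is far tighter
  se <- cfg$noise_sd * sqrt(1 / cfg$n_case + 1 / cfg$n_control)
  expect_lt(abs(mean(observed) - 1.5), 3 * se / sqrt(nrow(de)))
  null_lfc <- lfc$log2fc[!lfc$probe_id %in% de$probe_id]
  expect_lt(abs(mean(null_lfc)), 3 * se / sqrt(length(null_lfc)))
})

test_that("planted correlation concentrates on the target rho", {
  cfg <- synthetic_config(n_lnc = 600, n_mrna = 600, n_de_lnc = 0,
                          n_de_mrna = 0, n_linked_pairs = 500,
                          planted_rho = 0.85, n_cis_pairs = 0, seed = 31)
  g <- generate_expression(cfg)
  v <- g$expression$values
  r <- vapply(seq_len(500), function(i)
    cor(v[g$truth$linked_pairs$lnc_id[i], ],
        v[g$truth$linked_pairs$mrna_id[i], ]), numeric(1))
  expect_lt(abs(mean(r) - 0.85), 0.05)
})

test_that("annotation honors cis constraints and interval invariants", {
  cfg <- synthetic_config(n_lnc = 80, n_mrna = 120, n_de_lnc = 10,
                          n_de_mrna = 10, n_linked_pairs = 8,
                          n_cis_pairs = 5,
                          genome = setNames(rep(5e7, 3), paste0("chr", 1:3)),
                          seed = 41)
  g <- generate_expression(cfg)
  ann <- generate_annotation(cfg, g$truth)
  expect_setequal(ann$probe_id, rownames(g$expression$values))
  expect_true(all(ann$start >= 0 & ann$start < ann$end))
  expect_true(all(ann$end <= cfg$genome[ann$chrom]))

  linked <- g$truth$linked_pairs
  scan <- brute_force_cis(ann[match(linked$lnc_id, ann$probe_id), ],
                          ann[match(linked$mrna_id, ann$probe_id), ],
                          cfg$window_bp)
  # pairs the scan finds among linked pairs are exactly the designated cis set
  expect_setequal(pair_key(scan), pair_key(linked[linked$is_cis, ]))

  # and with no cis pairs configured the scan finds none
  cfg0 <- synthetic_config(n_lnc = 40, n_mrna = 40, n_de_lnc = 5,
                           n_de_mrna = 5, n_linked_pairs = 5,
                           n_cis_pairs = 0,
                           genome = setNames(rep(5e7, 3), paste0("chr", 1:3)),
                           seed = 42)
  g0 <- generate_expression(cfg0)
  ann0 <- generate_annotation(cfg0, g0$truth)
  l0 <- g0$truth$linked_pairs
  scan0 <- brute_force_cis(ann0[match(l0$lnc_id, ann0$probe_id), ],
                           ann0[match(l0$mrna_id, ann0$probe_id), ],
                           cfg0$window_bp)
  expect_equal(nrow(scan0), 0)
})

test_that("a genome too small for the layout raises a capacity error", {
  cfg <- synthetic_config(n_lnc = 50, n_mrna = 50, n_de_lnc = 0,
                          n_de_mrna = 0, n_linked_pairs = 0, n_cis_pairs = 0,
                          genome = c(chr1 = 1e6), seed = 5)
  g <- generate_expression(cfg)
  expect_error(generate_annotation(cfg, g$truth), "genome too small")
})

test_that("qPCR generator plants recoverable shifts", {
  cfg <- synthetic_config(n_lnc = 30, n_mrna = 30, n_de_lnc = 5,
                          n_de_mrna = 5, planted_log2fc = 1,
                          n_linked_pairs = 0, n_cis_pairs = 0, seed = 51)
  g <- generate_expression(cfg)
  de_target <- g$truth$de$probe_id[1]
  null_target <- "LNC00030"

  # zero-noise: exact arithmetic
  qp <- generate_qpcr(cfg, g$truth, c(de_target, null_target), ct_sd = 0)
  rel <- delta_delta_ct(qp)
  dir <- g$truth$de$direction[1]
  case_fold <- rel$fold[rel$gene_id == de_target & rel$group == "PDC"]
  expect_equal(unique(case_fold), 2^dir)
  expect_equal(unique(rel$fold[rel$gene_id == null_target]), 1)

  # unknown target rejected
  expect_error(generate_qpcr(cfg, g$truth, "NOPE"), "unknown qPCR target")

  # noisy recovery within 20% of planted, averaged over seeds
  folds <- vapply(1:100, function(s) {
    cfg_s <- synthetic_config(n_lnc = 30, n_mrna = 30, n_de_lnc = 5,
                              n_de_mrna = 5, planted_log2fc = 1,
                              n_linked_pairs = 0, n_cis_pairs = 0, seed = s)
    g_s <- generate_expression(cfg_s)
    tgt <- g_s$truth$de$probe_id[1]
    rel_s <- delta_delta_ct(generate_qpcr(cfg_s, g_s$truth, tgt, ct_sd = 0.2))
    2^(g_s$truth$de$direction[1] *
         mean(-rel_s$delta_delta_ct[rel_s$group == "PDC"]))
  }, numeric(1))
  expect_lt(abs(mean(folds) - 2), 0.4)
})
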