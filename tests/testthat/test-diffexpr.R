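test_that("log2 fold change and its linear-scale sign convention", {
  v <- rbind(c(3, 3, 2, 2), c(2, 2, 2, 2), c(1, 1, 2, 2))
  x <- tiny_expression(v, n_case = 2)
  lfc <- log2_fold_change(x)
  expect_equal(lfc$log2fc, c(1, 0, -1))
  expect_equal(lfc$fc, c(2, 1, -2))
  expect_true(all(abs(lfc$fc) >= 1))
})

test_that("prior fit: degenerate and null cases", {
  # constant variances: zero dispersion of log variances => no heterogeneity
  pr <- fit_moderation_prior(rep(0.25, 100), df = 20)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.25)

  expect_error(fit_moderation_prior(rep(0, 100), 20), "degenerate")

  # pure chi-square sampling variation (no between-probe component)
  set.seed(101)
  for (rep in 1:3) {
    pr <- fit_moderation_prior(0.25 * rchisq(5000, 20) / 20, df = 20)
    expect_true(is.infinite(pr$d0) || pr$d0 > 50)
  }
})

test_that("prior fit recovers a planted d0 and matches limma exactly", {
  set.seed(102)
  d0_hat <- replicate(20, fit_moderation_prior(0.3 * rf(5000, 20, 4), 20)$d0)
  expect_true(all(d0_hat > 2.5 & d0_hat < 6))

  s2 <- 0.3 * rf(2000, 20, 6)
  pr <- fit_moderation_prior(s2, 20)
  sq <- limma::squeezeVar(s2, 20)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-9)
  expect_equal(pr$s0_sq, sq$var.prior, tolerance = 1e-9)
  post <- (pr$d0 * pr$s0_sq + 20 * s2) / (pr$d0 + 20)
  expect_equal(post, sq$var.post, tolerance = 1e-9)
})

test_that("moderated t: shrinkage-free and full-shrinkage limits", {
  cfg <- synthetic_config(n_lnc = 100, n_mrna = 100, n_de_lnc = 10,
                          n_de_mrna = 10, n_linked_pairs = 0,
                          n_cis_pairs = 0, seed = 103)
  x <- generate_expression(cfg)$expression

  # d0 = 0 reproduces the ordinary pooled t probe by probe
  res0 <- moderated_t_test(x, prior = moderation_prior(0, 1))
  oracle <- pooled_t_oracle(x)
  expect_equal(res0$t_stat, unname(oracle[, "t"]), tolerance = 1e-12)
  expect_equal(res0$p_value, unname(oracle[, "p"]), tolerance = 1e-12)

  # d0 = Inf with s2 == s0_sq leaves every denominator at s0_sq
  v <- matrix(rnorm(50 * 22), 50)
  ca <- 1:13
  set.seed(108)
  v <- t(apply(v, 1L, function(r) {  # force pooled variance exactly 0.25
    r[ca] <- (r[ca] - mean(r[ca]))
    r[-ca] <- (r[-ca] - mean(r[-ca]))
    r <- r / sqrt(sum(r^2) / 20) * 0.5
    r[ca] <- r[ca] + rnorm(1)  # then restore distinct group means
    r
  }))
  x2 <- tiny_expression(v, n_case = 13)
  res_inf <- moderated_t_test(x2, prior = moderation_prior(Inf, 0.25))
  res_ord <- moderated_t_test(x2, prior = moderation_prior(0, 1))
  expect_equal(res_inf$t_stat, res_ord$t_stat, tolerance = 1e-10)
})

test_that("moderated t matches hand evaluation of the posterior formula", {
  set.seed(104)
  v <- rbind(c(rep(3, 13), rep(2, 9)) + rnorm(22, 0, 0.01),
             rnorm(22, 5, 0.3))
  x <- tiny_expression(v, n_case = 13)
  pr <- moderation_prior(4, 0.25)
  res <- moderated_t_test(x, prior = pr)
  for (i in 1:2) {
    a <- v[i, 1:13]; b <- v[i, 14:22]
    s2 <- (12 * var(a) + 8 * var(b)) / 20
    s2p <- (4 * 0.25 + 20 * s2) / 24
    t_hand <- (mean(a) - mean(b)) / sqrt(s2p * (1 / 13 + 1 / 9))
    expect_equal(res$t_stat[i], t_hand, tolerance = 1e-12)
    expect_equal(res$df_total[i], 24)
    expect_equal(res$p_value[i], 2 * pt(-abs(t_hand), 24), tolerance = 1e-12)
  }
})

test_that("|t| is strictly monotone in |log2fc| at fixed variance", {
  lfc <- seq(0.1, 2, by = 0.1)
  pr <- moderation_prior(4, 0.25)
  t_of <- function(l) l / sqrt(((4 * 0.25 + 20 * 0.25) / 24) * (1 / 13 + 1 / 9))
  ts <- vapply(lfc, t_of, numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("screening flag honors the non-strict FC and strict P convention", {
  # probes engineered around the thresholds
  de <- data.frame(probe_id = c("a", "b", "c"), biotype = "mRNA",
                   log2fc = c(log2(1.5), log2(1.4), log2(3)),
                   fc = c(1.5, 1.4, 3),
                   t_stat = 0, df_total = 24,
                   p_value = c(0.01, 0.01, 0.05), fdr = 1)
  is_de <- abs(de$fc) >= 1.5 & de$p_value < 0.05
  expect_equal(is_de, c(TRUE, FALSE, FALSE))  # fc boundary in, P boundary out
})

test_that("BH adjustment matches the brute-force step-up on small inputs", {
  set.seed(105)
  for (rep in 1:5) {
    p <- runif(sample(3:10, 1))
    expect_equal(p.adjust(p, "BH"), brute_force_bh(p), tolerance = 1e-12)
  }
  cfg <- synthetic_config(n_lnc = 30, n_mrna = 30, n_de_lnc = 0,
                          n_de_mrna = 0, n_linked_pairs = 0,
                          n_cis_pairs = 0, seed = 106)
  res <- moderated_t_test(generate_expression(cfg)$expression)
  expect_equal(res$fdr, brute_force_bh(res$p_value), tolerance = 1e-12)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("moderated t tracks limma eBayes end to end", {
  cfg <- synthetic_config(n_lnc = 150, n_mrna = 150, n_de_lnc = 20,
                          n_de_mrna = 20, n_linked_pairs = 0,
                          n_cis_pairs = 0, noise_sd = 0.4, seed = 107)
  x <- generate_expression(cfg)$expression
  # heterogeneous variances so the fitted d0 is finite
  set.seed(107)
  scale <- sqrt(rf(nrow(x$values), 20, 5))
  x$values <- x$values * scale  # scales both groups alike
  fit <- limma::eBayes(limma::lmFit(x$values,
                                    cbind(1, x$group == "PDC")))
  mine <- moderated_t_test(x)
  expect_equal(attr(mine, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mine$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})
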