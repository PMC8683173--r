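# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (quadratic scans, enumeration) so they share no code
# with the implementation under test.

# O(n^2) interval scan: all lnc x mrna pairs with span gap <= window
brute_force_cis <- function(lnc_loci, mrna_loci, window_bp) {
  hits <- list()
  for (i in seq_len(nrow(lnc_loci))) {
    for (j in seq_len(nrow(mrna_loci))) {
      if (lnc_loci$chrom[i] != mrna_loci$chrom[j]) next
      gap <- max(max(lnc_loci$start[i], mrna_loci$start[j]) -
                   min(lnc_loci$end[i], mrna_loci$end[j]), 0)
      if (gap <= window_bp)
        hits[[length(hits) + 1L]] <- data.frame(
          lnc_id = lnc_loci$probe_id[i], mrna_id = mrna_loci$probe_id[j],
          distance_bp = gap)
    }
  }
  if (!length(hits))
    return(data.frame(lnc_id = character(), mrna_id = character(),
                      distance_bp = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
}

# step-up BH by direct definition
brute_force_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# exact two-sided Mann-Whitney P by enumerating all label arrangements
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  u_of <- function(sel) {
    ra <- rank(pooled)[sel]
    sum(ra) - length(sel) * (length(sel) + 1) / 2
  }
  u_obs <- u_of(seq_along(a))
  u_all <- apply(idx, 2L, u_of)
  mu <- length(a) * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# ordinary pooled-variance two-sample t, probe by probe
pooled_t_oracle <- function(x) {
  ca <- case_samples(x); co <- control_samples(x)
  t(apply(x$values, 1L, function(v) {
    a <- v[ca]; b <- v[co]
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    c(t = tt, p = 2 * pt(-abs(tt), length(a) + length(b) - 2))
  }))
}

# small expression object built directly from a matrix
tiny_expression <- function(values, n_case, biotype = NULL) {
  n <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("S%02d", seq_len(n))
  if (is.null(biotype))
    biotype <- rep(c("lncRNA", "mRNA"), length.out = nrow(values))
  expression_matrix(values, biotype,
                    rep(c("PDC", "BC"), c(n_case, n - n_case)))
}

pair_key <- function(d) paste(d$lnc_id, d$mrna_id)
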