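#' Per-probe log2 fold change
#'
#' Fold change on the log2 scale is the difference of group means,
#' `mean(case) - mean(control)`. The signed linear fold change carries the
#' direction in its sign and the magnitude as `2^|log2fc|`, so `|fc| >= 1`
#' always and a null probe reports `+1`.
#'
#' @param x a `cnc_expression` object (values assumed log2).
#' @return data.frame with `probe_id`, `biotype`, `log2fc`, `fc`.
#' @export
log2_fold_change <- function(x) {
  stopifnot(inherits(x, "cnc_expression"))
  ca <- case_samples(x); co <- control_samples(x)
  if (length(ca) < 2L || length(co) < 2L)
    stop("each group needs >= 2 samples for a fold-change estimate")
  lfc <- rowMeans(x$values[, ca, drop = FALSE]) -
    rowMeans(x$values[, co, drop = FALSE])
  data.frame(probe_id = rownames(x$values), biotype = unname(x$biotype),
             log2fc = unname(lfc),
             fc = ifelse(lfc < 0, -1, 1) * 2^abs(unname(lfc)))
}

#' Construct a moderation prior
#'
#' Holds the empirical-Bayes shrinkage hyperparameters: prior degrees of
#' freedom `d0` (possibly infinite; 0 is the shrinkage-free limit in which
#' the moderated test reduces to the ordinary pooled t) and prior variance
#' `s0_sq` on the squared log2 scale.
#'
#' @param d0 prior degrees of freedom, `>= 0` or `Inf`.
#' @param s0_sq prior variance, `> 0`.
#' @return object of class `moderation_prior`.
#' @export
moderation_prior <- function(d0, s0_sq) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0)
    stop("d0 must be a single value >= 0 (possibly Inf)")
  if (!is.numeric(s0_sq) || length(s0_sq) != 1L || !is.finite(s0_sq) ||
      s0_sq <= 0)
    stop("s0_sq must be a single positive value")
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat("moderation_prior: d0 =", format(x$d0), " s0_sq =",
      format(x$s0_sq), "\n")
  invisible(x)
}

# Newton inversion of trigamma(x) = y, with asymptotic guards for extreme y
.trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1L))
}

#' Fit the variance-moderation prior by moments
#'
#' Empirical-Bayes method of moments on the log sample variances: assuming
#' `s^2 ~ s0^2 * F(d, d0)` across probes, the mean and variance of
#' `log(s^2)` are matched using digamma/trigamma identities, and the
#' trigamma equation for `d0` is inverted numerically. When the observed
#' dispersion of log variances does not exceed what the within-probe
#' chi-square sampling alone produces, there is no evidence of between-probe
#' variance heterogeneity and `d0 = Inf` with `s0_sq` the mean variance.
#'
#' @param s2 per-probe sample variances (pooled residual variances).
#' @param df residual degrees of freedom shared by all probes
#'   (`n_case + n_control - 2`).
#' @return a [moderation_prior()].
#' @export
fit_moderation_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (all(s2 <= 0)) stop("degenerate data: all sample variances are zero")
  s2 <- s2[s2 > 0]
  if (length(s2) < 30L)
    stop("need >= 30 positive sample variances to fit the prior")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  excess <- mean((e - e_mean)^2) * length(e) / (length(e) - 1L) -
    trigamma(df / 2)
  if (excess <= 0)
    return(moderation_prior(Inf, mean(s2)))
  half_d0 <- .trigamma_inverse(excess)
  d0 <- 2 * half_d0
  s0_sq <- exp(e_mean + digamma(half_d0) - log(half_d0))
  moderation_prior(d0, s0_sq)
}

# df cap standing in for an infinite-d0 t distribution (normal to numerical
# precision at 1e6 df)
.D0_CAP <- 1e6

#' Moderated two-sample t-test with fold-change screening
#'
#' For each probe the pooled residual variance is shrunk toward the prior:
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)`, the moderated statistic is
#' `t = log2fc / (s_post * sqrt(1/n1 + 1/n2))`, and the two-sided P comes
#' from a t distribution on `d + d0` degrees of freedom (`d0 = Inf` is
#' handled by a large-df cap). `d0 = 0` reproduces the ordinary
#' pooled-variance t-test.
#'
#' The screening flag follows the conventional array filter: a probe is
#' called differentially expressed when `|fc| >= fc_threshold` (non-strict,
#' linear scale) and `p_value < p_threshold` (strict, raw P). BH-adjusted
#' FDR is reported over all probes jointly but does not enter the filter.
#'
#' @param x a `cnc_expression` object.
#' @param prior a [moderation_prior()]; fitted from the data with
#'   [fit_moderation_prior()] when `NULL`.
#' @param fc_threshold linear fold-change cutoff (default 1.5).
#' @param p_threshold raw P cutoff (default 0.05).
#' @return data.frame (rows in probe order) with `probe_id`, `biotype`,
#'   `log2fc`, `fc`, `t_stat`, `df_total`, `p_value`, `fdr`, `is_de`, plus
#'   the fitted prior in attribute `"prior"`.
#' @export
moderated_t_test <- function(x, prior = NULL, fc_threshold = 1.5,
                             p_threshold = 0.05) {
  stopifnot(inherits(x, "cnc_expression"))
  ca <- case_samples(x); co <- control_samples(x)
  n1 <- length(ca); n2 <- length(co)
  d <- n1 + n2 - 2L
  lfc_tab <- log2_fold_change(x)

  v1 <- .row_vars(x$values[, ca, drop = FALSE])
  v2 <- .row_vars(x$values[, co, drop = FALSE])
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (is.null(prior)) prior <- fit_moderation_prior(s2, d)
  stopifnot(inherits(prior, "moderation_prior"))

  d0 <- min(prior$d0, .D0_CAP)
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(s2)) else
    (d0 * prior$s0_sq + d * s2) / (d0 + d)
  if (any(s2_post <= 0)) stop("zero posterior variance encountered")
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- lfc_tab$log2fc / se
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  res <- data.frame(
    probe_id = lfc_tab$probe_id, biotype = lfc_tab$biotype,
    log2fc = lfc_tab$log2fc, fc = lfc_tab$fc,
    t_stat = t_stat, df_total = df_total, p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    is_de = abs(lfc_tab$fc) >= fc_threshold & p < p_threshold)
  attr(res, "prior") <- prior
  res
}

.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Per-probe Welch t-test
#'
#' Unequal-variance two-sample t with Satterthwaite degrees of freedom; the
#' standalone alternative to the moderated pooled test.
#'
#' @param x a `cnc_expression` object.
#' @return data.frame with `probe_id`, `t_stat`, `df`, `p_value`.
#' @export
welch_t_test <- function(x) {
  stopifnot(inherits(x, "cnc_expression"))
  ca <- case_samples(x); co <- control_samples(x)
  n1 <- length(ca); n2 <- length(co)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(x$values[, ca, drop = FALSE])
  m2 <- rowMeans(x$values[, co, drop = FALSE])
  v1 <- .row_vars(x$values[, ca, drop = FALSE])
  v2 <- .row_vars(x$values[, co, drop = FALSE])
  se2 <- v1 / n1 + v2 / n2
  if (any(se2 == 0))
    stop("undefined statistic: zero variance in both groups for probe(s) ",
         paste(utils::head(rownames(x$values)[se2 == 0], 3L), collapse = ", "))
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  data.frame(probe_id = rownames(x$values), t_stat = unname(t_stat),
             df = unname(df),
             p_value = unname(2 * stats::pt(-abs(t_stat), df)))
}

#' Mann-Whitney U test
#'
#' Exact two-sided P by enumeration when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie and continuity correction. U is reported for the first sample.
#'
#' @param a,b numeric vectors (the two groups).
#' @return list with `U` and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    stop("undefined statistic: all pooled values identical")
  use_exact <- (length(a) + length(b)) <= 12L && !anyDuplicated(pooled)
  w <- stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  list(U = unname(w$statistic), p_value = w$p.value)
}

#' Paired t-test
#'
#' @param before,after numeric vectors of equal length, matched by position.
#' @return list with `t_stat`, `df`, `p_value`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    stop("paired samples must have equal length")
  d <- before - after
  if (stats::sd(d) == 0)
    stop("undefined statistic: zero variance of paired differences")
  tt <- stats::t.test(before, after, paired = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
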