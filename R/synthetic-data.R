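#' Configuration for the synthetic two-group microarray emulator
#'
#' Defaults mirror the study design the pipeline targets: 13 case (PDC)
#' vs 9 control (BC) samples, a probe set dominated by mRNA probes, and a
#' handful of planted effects. The full-scale array (22,621 lncRNA and
#' 31,860 mRNA probes) is emulated at one-tenth scale by default; pass the
#' full counts to reproduce the original dimensions.
#'
#' @param n_case,n_control samples per group (defaults 13 and 9).
#' @param n_lnc,n_mrna number of lncRNA / mRNA probes (defaults 2262, 3186).
#' @param n_de_lnc,n_de_mrna planted differentially expressed probes per
#'   biotype (defaults 40 and 44).
#' @param planted_log2fc planted group-mean difference in log2 units
#'   (default 1.5, i.e. a linear fold change of 2^1.5 ~ 2.83).
#' @param noise_sd within-group standard deviation, log2 units (default 0.5).
#' @param n_linked_pairs planted coexpressed lncRNA-mRNA pairs (default 50).
#' @param planted_rho target Pearson correlation of linked pairs (default 0.85).
#' @param n_cis_pairs how many linked pairs are additionally placed within
#'   the cis window on the same chromosome (default 12).
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param window_bp cis window, bp (default 300000).
#' @param baseline constant baseline expression, log2 units (default 8).
#' @param seed integer RNG seed.
#' @return a validated list of class `cnc_config`.
#' @export
synthetic_config <- function(n_case = 13, n_control = 9,
                             n_lnc = 2262, n_mrna = 3186,
                             n_de_lnc = 40, n_de_mrna = 44,
                             planted_log2fc = 1.5, noise_sd = 0.5,
                             n_linked_pairs = 50, planted_rho = 0.85,
                             n_cis_pairs = 12,
                             genome = stats::setNames(rep(1.2e8, 25),
                                                      paste0("chr", 1:25)),
                             window_bp = 300000, baseline = 8,
                             seed = 1L) {
  cfg <- list(n_case = n_case, n_control = n_control, n_lnc = n_lnc,
              n_mrna = n_mrna, n_de_lnc = n_de_lnc, n_de_mrna = n_de_mrna,
              planted_log2fc = planted_log2fc, noise_sd = noise_sd,
              n_linked_pairs = n_linked_pairs, planted_rho = planted_rho,
              n_cis_pairs = n_cis_pairs, genome = genome,
              window_bp = window_bp, baseline = baseline,
              seed = as.integer(seed))
  for (f in c("n_case", "n_control", "n_lnc", "n_mrna", "n_de_lnc",
              "n_de_mrna", "n_linked_pairs", "n_cis_pairs")) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop("invalid config field '", f, "': must be a non-negative count")
  }
  if (cfg$n_case < 2 || cfg$n_control < 2)
    stop("invalid config field 'n_case'/'n_control': need >= 2 per group")
  if (cfg$n_de_lnc > cfg$n_lnc)
    stop("invalid config field 'n_de_lnc': exceeds n_lnc")
  if (cfg$n_de_mrna > cfg$n_mrna)
    stop("invalid config field 'n_de_mrna': exceeds n_mrna")
  if (cfg$n_linked_pairs > min(cfg$n_lnc, cfg$n_mrna))
    stop("invalid config field 'n_linked_pairs': exceeds probe counts")
  if (cfg$n_cis_pairs > cfg$n_linked_pairs)
    stop("invalid config field 'n_cis_pairs': exceeds n_linked_pairs")
  if (!is.finite(cfg$planted_rho) || cfg$planted_rho < 0 || cfg$planted_rho >= 1)
    stop("invalid config field 'planted_rho': need 0 <= rho < 1")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("invalid config field 'noise_sd': must be > 0")
  if (!length(cfg$genome) || is.null(names(cfg$genome)) ||
      any(cfg$genome <= 0))
    stop("invalid config field 'genome': named positive chromosome lengths")
  if (cfg$window_bp < 0)
    stop("invalid config field 'window_bp': must be >= 0")
  class(cfg) <- "cnc_config"
  cfg
}

# probe id scheme shared by every generator
.probe_ids <- function(cfg) {
  c(sprintf("LNC%05d", seq_len(cfg$n_lnc)),
    sprintf("MRNA%05d", seq_len(cfg$n_mrna)))
}

#' Generate a synthetic expression matrix with planted truth
#'
#' Null probes are i.i.d. Normal(baseline, noise_sd^2) in both groups.
#' Planted DE probes (the first `n_de_*` of each biotype) get a group-mean
#' shift of `planted_log2fc` with a random sign. Planted linked pairs
#' (pair i couples lncRNA i with mRNA i) are drawn from a bivariate normal
#' with correlation `planted_rho`; the correlation is induced across all
#' samples first and group shifts are added afterwards, so `planted_rho` is
#' a within-population correlation. Linked pairs landing on two planted-DE
#' probes get concordant DE directions so the group shift does not cancel
#' the planted (positive) correlation.
#'
#' RNG: a single stream seeded from `config$seed`, consumed in the fixed
#' order (DE directions lncRNA, DE directions mRNA, noise matrix); identical
#' config and seed give bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with `expression` (a `cnc_expression`) and `truth`
#'   (class `cnc_truth`: data.frames `de` with `probe_id`, `biotype`,
#'   `direction`, and `linked_pairs` with `lnc_id`, `mrna_id`, `rho`,
#'   `is_cis`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "cnc_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_probes <- cfg$n_lnc + cfg$n_mrna
  n_samples <- cfg$n_case + cfg$n_control
  probes <- .probe_ids(cfg)
  samples <- c(sprintf("PDC%02d", seq_len(cfg$n_case)),
               sprintf("BC%02d", seq_len(cfg$n_control)))
  group <- rep(c("PDC", "BC"), c(cfg$n_case, cfg$n_control))
  biotype <- rep(c("lncRNA", "mRNA"), c(cfg$n_lnc, cfg$n_mrna))

  dir_lnc <- if (cfg$n_de_lnc) sample(c(-1, 1), cfg$n_de_lnc, replace = TRUE) else numeric()
  dir_mrna <- if (cfg$n_de_mrna) sample(c(-1, 1), cfg$n_de_mrna, replace = TRUE) else numeric()
  # concordant directions for linked pairs where both members are planted DE
  n_both <- min(cfg$n_linked_pairs, cfg$n_de_lnc, cfg$n_de_mrna)
  if (n_both > 0) dir_mrna[seq_len(n_both)] <- dir_lnc[seq_len(n_both)]

  z <- matrix(stats::rnorm(n_probes * n_samples), n_probes, n_samples)
  if (cfg$n_linked_pairs > 0) {
    li <- seq_len(cfg$n_linked_pairs)            # lncRNA rows
    mi <- cfg$n_lnc + seq_len(cfg$n_linked_pairs) # paired mRNA rows
    z[mi, ] <- cfg$planted_rho * z[li, ] +
      sqrt(1 - cfg$planted_rho^2) * z[mi, ]
  }
  vals <- cfg$baseline + cfg$noise_sd * z
  case_cols <- seq_len(cfg$n_case)
  if (cfg$n_de_lnc > 0)
    vals[seq_len(cfg$n_de_lnc), case_cols] <-
      vals[seq_len(cfg$n_de_lnc), case_cols] + cfg$planted_log2fc * dir_lnc
  if (cfg$n_de_mrna > 0)
    vals[cfg$n_lnc + seq_len(cfg$n_de_mrna), case_cols] <-
      vals[cfg$n_lnc + seq_len(cfg$n_de_mrna), case_cols] +
      cfg$planted_log2fc * dir_mrna
  dimnames(vals) <- list(probes, samples)

  de <- data.frame(
    probe_id = c(probes[seq_len(cfg$n_de_lnc)],
                 probes[cfg$n_lnc + seq_len(cfg$n_de_mrna)]),
    biotype = rep(c("lncRNA", "mRNA"), c(cfg$n_de_lnc, cfg$n_de_mrna)),
    direction = c(dir_lnc, dir_mrna))
  linked <- data.frame(
    lnc_id = probes[seq_len(cfg$n_linked_pairs)],
    mrna_id = probes[cfg$n_lnc + seq_len(cfg$n_linked_pairs)],
    rho = rep(cfg$planted_rho, cfg$n_linked_pairs),
    is_cis = seq_len(cfg$n_linked_pairs) <= cfg$n_cis_pairs)
  if (cfg$n_linked_pairs == 0)
    linked <- data.frame(lnc_id = character(), mrna_id = character(),
                         rho = numeric(), is_cis = logical())
  truth <- structure(list(de = de, linked_pairs = linked), class = "cnc_truth")
  list(expression = expression_matrix(vals, biotype, group),
       truth = truth)
}

#' Generate genomic loci honoring planted cis relations
#'
#' Every probe receives a 1 kb interval. Probes are laid out left to right
#' across the configured genome with inter-unit gaps strictly larger than
#' the cis window, so by construction no two distinct placement units fall
#' within `window_bp` of each other. A designated cis pair is placed as a
#' single unit: its mRNA starts a uniformly drawn gap (0..window_bp,
#' boundary inclusive) downstream of its lncRNA, so the pair distance is
#' within the window while every non-cis pair is either on a different
#' chromosome or farther than the window away.
#'
#' @param config a [synthetic_config()].
#' @param truth the `cnc_truth` from [generate_expression()].
#' @param gene_length interval length per probe, bp (default 1000).
#' @return data.frame of loci (as [read_bed()] returns): `probe_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @export
generate_annotation <- function(config, truth, gene_length = 1000) {
  stopifnot(inherits(config, "cnc_config"), inherits(truth, "cnc_truth"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  probes <- .probe_ids(cfg)
  cis <- truth$linked_pairs[truth$linked_pairs$is_cis, , drop = FALSE]

  # placement units: cis pairs first (two probes each), then the rest singly
  paired <- c(cis$lnc_id, cis$mrna_id)
  singles <- setdiff(probes, paired)
  n_units <- nrow(cis) + length(singles)

  chrom_names <- names(cfg$genome)
  chrom_len <- unname(cfg$genome)
  ci <- 1L
  cursor <- 0
  res_chrom <- character(cfg$n_lnc + cfg$n_mrna)
  res_start <- numeric(cfg$n_lnc + cfg$n_mrna)
  names(res_start) <- probes
  names(res_chrom) <- probes

  place_unit <- function(width) {
    # returns (chrom index, start) advancing the shared cursor
    gap <- cfg$window_bp + 1 + sample.int(50000L, 1L)
    repeat {
      start <- cursor + gap
      if (start + width <= chrom_len[ci]) {
        cursor <<- start + width
        return(c(ci, start))
      }
      ci <<- ci + 1L
      cursor <<- 0
      gap <- sample.int(50000L, 1L)  # fresh chromosome: no carried gap needed
      if (ci > length(chrom_names))
        stop("genome too small to place all probes with the required spacing")
    }
  }

  for (i in seq_len(nrow(cis))) {
    pair_gap <- sample.int(cfg$window_bp + 1L, 1L) - 1L  # 0..window_bp inclusive
    unit_width <- 2 * gene_length + pair_gap
    at <- place_unit(unit_width)
    res_chrom[cis$lnc_id[i]] <- chrom_names[at[1L]]
    res_start[cis$lnc_id[i]] <- at[2L]
    res_chrom[cis$mrna_id[i]] <- chrom_names[at[1L]]
    res_start[cis$mrna_id[i]] <- at[2L] + gene_length + pair_gap
  }
  for (p in singles) {
    at <- place_unit(gene_length)
    res_chrom[p] <- chrom_names[at[1L]]
    res_start[p] <- at[2L]
  }
  data.frame(probe_id = probes, chrom = unname(res_chrom[probes]),
             start = unname(res_start[probes]),
             end = unname(res_start[probes]) + gene_length,
             strand = sample(c("+", "-"), length(probes), replace = TRUE))
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates single-reference RT-qPCR of selected validation targets. Each
#' sample gets a loading offset shared by all its wells (cancelled by
#' delta-Ct normalization); target Ct is shifted by `-planted_log2fc *
#' direction` in the case group for planted DE targets (Ct falls as
#' abundance rises); the reference gene has constant expected Ct across
#' groups.
#'
#' @param config a [synthetic_config()].
#' @param truth the `cnc_truth` from [generate_expression()].
#' @param targets probe ids to assay (must exist in the design).
#' @param n_case,n_control cohort sizes for the validation experiment;
#'   default to a 9 case vs 12 control design, the conventional smaller
#'   follow-up cohort (override to match the array design if desired).
#' @param ct_sd technical noise SD in cycles (default `config$noise_sd`;
#'   may be 0 for exact arithmetic checks).
#' @param reference_gene name of the housekeeping gene (default `"ACTB"`).
#' @return data.frame with columns `sample_id`, `group`, `gene`, `ct`.
#' @export
generate_qpcr <- function(config, truth, targets,
                          n_case = 9, n_control = 12,
                          ct_sd = config$noise_sd,
                          reference_gene = "ACTB") {
  stopifnot(inherits(config, "cnc_config"), inherits(truth, "cnc_truth"))
  probes <- .probe_ids(config)
  unknown <- setdiff(targets, probes)
  if (length(unknown))
    stop("unknown qPCR target id(s): ", paste(unknown, collapse = ", "))
  set.seed(config$seed + 2L)
  samples <- c(sprintf("V_PDC%02d", seq_len(n_case)),
               sprintf("V_BC%02d", seq_len(n_control)))
  group <- rep(c("PDC", "BC"), c(n_case, n_control))
  is_case <- group == "PDC"
  loading <- stats::rnorm(length(samples), 0, ct_sd)

  shift <- stats::setNames(rep(0, length(targets)), targets)
  hit <- intersect(targets, truth$de$probe_id)
  shift[hit] <- config$planted_log2fc *
    truth$de$direction[match(hit, truth$de$probe_id)]

  rows <- lapply(c(reference_gene, targets), function(g) {
    base_ct <- if (g == reference_gene) 15 else 25
    ct <- base_ct + loading + stats::rnorm(length(samples), 0, ct_sd)
    if (g != reference_gene) ct[is_case] <- ct[is_case] - shift[g]
    data.frame(sample_id = samples, group = group, gene = g, ct = ct)
  })
  do.call(rbind, rows)
}
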