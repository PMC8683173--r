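#' Genomic distance between two loci
#'
#' Distance is the minimum gap between the two gene spans in bp: 0 for
#' overlapping or abutting intervals, `NA` ("not comparable") for loci on
#' different chromosomes. Coordinates are 0-based half-open (BED).
#' Symmetric in its arguments and strand-agnostic.
#'
#' @param a,b loci: data.frames (or one-row slices) with `chrom`, `start`,
#'   `end`; vectorized elementwise over rows.
#' @return numeric distance(s) in bp, `NA` where chromosomes differ.
#' @export
genomic_distance <- function(a, b) {
  d <- pmax(pmax(a$start, b$start) - pmin(a$end, b$end), 0)
  d[a$chrom != b$chrom] <- NA_real_
  d
}

#' Find lncRNA-mRNA pairs within a cis window
#'
#' All (lncRNA locus, mRNA locus) pairs on the same chromosome whose span
#' gap is at most `window_bp` ("within 300 kb" reads as a non-strict bound,
#' so a pair at exactly the window distance is included; overlapping genes
#' are at distance 0). Backed by the GenomicRanges interval index; results
#' are identical to an exhaustive quadratic scan.
#'
#' @param lnc_loci,mrna_loci locus data.frames ([read_bed()] layout) for the
#'   lncRNA and coding-gene probes of interest.
#' @param window_bp window size in bp, inclusive (default 300000).
#' @return data.frame of class-free cis pairs: `lnc_id`, `mrna_id`, `chrom`,
#'   `distance_bp`, `same_strand`, sorted by `(lnc_id, mrna_id)`.
#' @export
find_cis_pairs <- function(lnc_loci, mrna_loci, window_bp = 300000) {
  empty <- data.frame(lnc_id = character(), mrna_id = character(),
                      chrom = character(), distance_bp = numeric(),
                      same_strand = logical())
  if (!nrow(lnc_loci) || !nrow(mrna_loci)) {
    warning("empty locus list; no cis pairs")
    return(empty)
  }
  gr <- function(loci) GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  gl <- gr(lnc_loci); gm <- gr(mrna_loci)
  hits <- GenomicRanges::findOverlaps(gl, gm, maxgap = window_bp,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(empty)
  dist <- GenomicRanges::distance(gl[qi], gm[si])
  keep <- !is.na(dist) & dist <= window_bp
  qi <- qi[keep]; si <- si[keep]; dist <- dist[keep]
  out <- data.frame(
    lnc_id = lnc_loci$probe_id[qi], mrna_id = mrna_loci$probe_id[si],
    chrom = lnc_loci$chrom[qi], distance_bp = as.numeric(dist),
    same_strand = lnc_loci$strand[qi] == mrna_loci$strand[si] &
      lnc_loci$strand[qi] %in% c("+", "-"))
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect cis pairs with the coexpression network
#'
#' The cis-target call of the pipeline: a coding gene is a predicted cis
#' target of a lncRNA when the pair is both within the genomic window and a
#' passing edge of the CNC network. Each retained pair carries the edge's
#' correlation statistics and the genomic distance.
#'
#' @param cis_pairs data.frame from [find_cis_pairs()].
#' @param network a `cnc_network`.
#' @return data.frame `lnc_id`, `mrna_id`, `chrom`, `distance_bp`, `pcc`,
#'   `p_value`; zero rows when the sets are disjoint.
#' @export
intersect_cis_coexpressed <- function(cis_pairs, network) {
  stopifnot(inherits(network, "cnc_network"))
  merged <- merge(cis_pairs, network$edges, by = c("lnc_id", "mrna_id"))
  out <- merged[, c("lnc_id", "mrna_id", "chrom", "distance_bp",
                    "pcc", "p_value")]
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-lncRNA count of nearby coding genes
#'
#' @param cis_pairs data.frame from [find_cis_pairs()] (or the intersected
#'   table).
#' @return data.frame `lnc_id`, `n_nearby_coding_genes`.
#' @export
cis_summary <- function(cis_pairs) {
  tab <- table(cis_pairs$lnc_id)
  data.frame(lnc_id = names(tab),
             n_nearby_coding_genes = as.integer(tab))
}
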