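#' Read a qPCR Ct table
#'
#' CSV with columns `sample_id`, `group`, `gene`, `ct`. Technical
#' replicates (repeated `(sample, gene)` rows) are averaged; Ct values must
#' be finite and positive.
#'
#' @param path CSV path.
#' @return data.frame with one row per `(sample, gene)`.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path)
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(tab)))
    stop("qPCR CSV must have columns ", paste(need, collapse = ", "))
  tab$ct <- as.numeric(tab$ct)
  if (any(!is.finite(tab$ct) | tab$ct <= 0))
    stop("Ct values must be finite and > 0")
  key <- paste(tab$sample_id, tab$gene, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(ct ~ sample_id + group + gene, tab, mean)
    message("averaged technical replicates for ",
            sum(duplicated(key)), " well(s)")
    tab <- agg
  }
  tab[, need]
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample: `dCt = Ct(gene) - Ct(reference)`; per gene:
#' `ddCt = dCt - mean(control-group dCt)`, `fold = 2^(-ddCt)`. The
#' control-group mean ddCt is therefore 0 by construction (the control
#' geometric-mean fold is 1). Any constant added to every Ct of a sample
#' cancels in dCt.
#'
#' @param records qPCR table as from [read_qpcr()] or [generate_qpcr()].
#' @param reference_gene housekeeping gene id (default `"ACTB"`).
#' @param control_label group label of the control/baseline group
#'   (default `"BC"`).
#' @return data.frame with `sample_id`, `group`, `gene_id`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
delta_delta_ct <- function(records, reference_gene = "ACTB",
                           control_label = "BC") {
  ref <- records[records$gene == reference_gene, , drop = FALSE]
  if (!nrow(ref)) stop("no Ct records for reference gene '",
                       reference_gene, "'")
  targ <- records[records$gene != reference_gene, , drop = FALSE]
  missing_ref <- setdiff(unique(targ$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    warning("dropping sample(s) without reference-gene Ct: ",
            paste(missing_ref, collapse = ", "))
    targ <- targ[!targ$sample_id %in% missing_ref, , drop = FALSE]
  }
  if (sum(unique(records$sample_id) %in%
          records$sample_id[records$group == control_label]) < 2L)
    stop("need >= 2 control ('", control_label, "') samples")
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  targ$delta_ct <- targ$ct - ref_ct[targ$sample_id]
  out <- do.call(rbind, lapply(split(targ, targ$gene), function(d) {
    base <- mean(d$delta_ct[d$group == control_label])
    d$delta_delta_ct <- d$delta_ct - base
    d
  }))
  out$fold <- 2^(-out$delta_delta_ct)
  res <- data.frame(sample_id = out$sample_id, group = out$group,
                    gene_id = out$gene, delta_ct = out$delta_ct,
                    delta_delta_ct = out$delta_delta_ct, fold = out$fold)
  res <- res[order(res$gene_id, res$sample_id), ]
  rownames(res) <- NULL
  res
}

#' Per-gene case-vs-control comparison of qPCR relative expression
#'
#' Tests run on the delta-Ct values (log2-abundance scale, closer to
#' normal); the reported direction comes from the fold values: `+1` when
#' the case-group mean fold exceeds the control-group mean fold
#' (upregulated in cases), else `-1`.
#'
#' @param rel table from [delta_delta_ct()].
#' @param method `"t"` (Welch, default) or `"mann-whitney"`.
#' @param case_label,control_label group labels.
#' @return data.frame with `gene_id`, `statistic`, `p_value`, `direction`,
#'   `mean_fold_case`, `mean_fold_control`.
#' @export
group_compare <- function(rel, method = c("t", "mann-whitney"),
                          case_label = "PDC", control_label = "BC") {
  method <- match.arg(method)
  rows <- lapply(split(rel, rel$gene_id), function(d) {
    ca <- d[d$group == case_label, ]
    co <- d[d$group == control_label, ]
    if (!nrow(ca) || !nrow(co)) {
      warning("gene '", d$gene_id[1L], "' present in only one group; skipped")
      return(NULL)
    }
    if (method == "t") {
      tt <- stats::t.test(ca$delta_ct, co$delta_ct)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      mw <- mann_whitney(ca$delta_ct, co$delta_ct)
      stat <- mw$U; p <- mw$p_value
    }
    data.frame(gene_id = d$gene_id[1L], statistic = stat, p_value = p,
               direction = ifelse(mean(ca$fold) >= mean(co$fold), 1, -1),
               mean_fold_case = mean(ca$fold),
               mean_fold_control = mean(co$fold))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Direction concordance between qPCR and array calls
#'
#' Fraction of shared genes whose qPCR direction (up/down in cases)
#' matches the array's differential-expression direction.
#'
#' @param qpcr_directions named numeric vector of qPCR directions (+1/-1),
#'   names = gene ids (e.g. from [group_compare()]).
#' @param array_directions named numeric vector of array directions
#'   (sign of log2fc).
#' @param genes optional gene subset; defaults to the shared names.
#' @return list with `fraction` and a per-gene data.frame `table`.
#' @export
concordance <- function(qpcr_directions, array_directions, genes = NULL) {
  if (is.null(genes))
    genes <- intersect(names(qpcr_directions), names(array_directions))
  if (!length(genes)) stop("no shared genes between qPCR and array results")
  agree <- sign(qpcr_directions[genes]) == sign(array_directions[genes])
  list(fraction = mean(agree),
       table = data.frame(gene_id = genes,
                          qpcr_direction = unname(sign(qpcr_directions[genes])),
                          array_direction = unname(sign(array_directions[genes])),
                          agree = unname(agree)))
}
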