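#' Construct an expression matrix container
#'
#' The central data container of the pipeline: a numeric matrix of
#' normalized log2 intensities (probes in rows, samples in columns) together
#' with a probe biotype (`"lncRNA"` or `"mRNA"`) and a two-group sample
#' assignment (case vs control).
#'
#' @param values numeric matrix of log2 intensities; rownames are probe ids,
#'   colnames are sample ids.
#' @param biotype character vector, one of `"lncRNA"`/`"mRNA"` per probe,
#'   in row order (or named by probe id).
#' @param group character vector of group labels per sample, in column order
#'   (or named by sample id). Exactly the two labels `case_label` and
#'   `control_label` must occur, each at least twice.
#' @param case_label,control_label the labels identifying the case and
#'   control groups (defaults `"PDC"` and `"BC"`).
#' @param gene_symbol optional character vector mapping probes to gene
#'   symbols (used as gene identity in enrichment); defaults to probe ids.
#'
#' @return An object of class `cnc_expression`: a list with elements
#'   `values`, `biotype`, `group`, `case_label`, `control_label`,
#'   `gene_symbol`.
#' @export
expression_matrix <- function(values, biotype, group,
                              case_label = "PDC", control_label = "BC",
                              gene_symbol = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix of log2 intensities")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probe ids as rownames and sample ids as colnames")
  probes <- rownames(values)
  samples <- colnames(values)
  if (anyDuplicated(probes))
    stop("duplicate probe id(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite; missing/non-numeric cells are rejected")

  biotype <- .match_named(biotype, probes, "biotype", "probe")
  if (!all(biotype %in% c("lncRNA", "mRNA")))
    stop("biotype must be 'lncRNA' or 'mRNA'")
  group <- .match_named(group, samples, "group", "sample")
  if (!setequal(unique(group), c(case_label, control_label)))
    stop("sample groups must be exactly {", case_label, ", ", control_label,
         "}; got {", paste(unique(group), collapse = ", "), "}")
  n_case <- sum(group == case_label)
  n_ctrl <- sum(group == control_label)
  if (n_case < 2L || n_ctrl < 2L)
    stop("each group needs at least 2 samples (case: ", n_case,
         ", control: ", n_ctrl, ")")
  if (is.null(gene_symbol)) gene_symbol <- probes
  gene_symbol <- .match_named(gene_symbol, probes, "gene_symbol", "probe")

  structure(
    list(values = values, biotype = biotype, group = group,
         case_label = case_label, control_label = control_label,
         gene_symbol = gene_symbol),
    class = "cnc_expression"
  )
}

# align a per-probe/per-sample vector with the matrix margin, by name if named
.match_named <- function(x, ids, what, margin) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop(what, " missing for ", margin, "(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop("'", what, "' must have one entry per ", margin,
         " (got ", length(x), ", need ", length(ids), ")")
  }
  stats::setNames(as.character(x), ids)
}

#' @export
print.cnc_expression <- function(x, ...) {
  cat("cnc_expression: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  biotype: ", sum(x$biotype == "lncRNA"), " lncRNA, ",
      sum(x$biotype == "mRNA"), " mRNA\n", sep = "")
  cat("  groups:  ", sum(x$group == x$case_label), " ", x$case_label,
      " (case) vs ", sum(x$group == x$control_label), " ", x$control_label,
      " (control)\n", sep = "")
  invisible(x)
}

#' Case and control sample ids of an expression matrix
#' @param x a `cnc_expression` object.
#' @return character vector of sample ids.
#' @export
case_samples <- function(x) names(x$group)[x$group == x$case_label]

#' @rdname case_samples
#' @export
control_samples <- function(x) names(x$group)[x$group == x$control_label]
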