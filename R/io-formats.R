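#' Read an expression matrix and sample metadata
#'
#' The expression TSV has probes as rows: first column `probe_id`, second
#' column `biotype` (`lncRNA`/`mRNA`), optional `gene_symbol` column, then
#' one numeric column per sample (header row carries sample ids). The
#' metadata CSV has columns `sample_id` and `group` and must cover every
#' sample column of the TSV.
#'
#' Malformed input (duplicate ids, missing groups, non-numeric cells,
#' a group with fewer than 2 samples) is rejected with an error naming the
#' offending id; nothing is silently coerced.
#'
#' @param expression_tsv path to the expression TSV.
#' @param metadata_csv path to the sample metadata CSV.
#' @param case_label,control_label group labels (defaults `"PDC"`, `"BC"`).
#' @param drop_incomplete drop probes containing missing/non-numeric values
#'   (with a warning) instead of rejecting the file (default `FALSE`: the
#'   analysis assumes complete matrices).
#' @return a [expression_matrix()] object.
#' @export
read_expression <- function(expression_tsv, metadata_csv,
                            case_label = "PDC", control_label = "BC",
                            drop_incomplete = FALSE) {
  for (f in c(expression_tsv, metadata_csv))
    if (!file.exists(f)) stop("file not found: ", f)
  tab <- utils::read.delim(expression_tsv, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!identical(names(tab)[1:2], c("probe_id", "biotype")))
    stop("expression TSV must start with columns 'probe_id' and 'biotype'")
  sym <- NULL
  data_cols <- seq(3L, ncol(tab))
  if (ncol(tab) >= 3L && names(tab)[3L] == "gene_symbol") {
    sym <- tab$gene_symbol
    data_cols <- data_cols[-1L]
  }
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe id in expression TSV: ",
         paste(unique(tab$probe_id[duplicated(tab$probe_id)]), collapse = ", "))
  vals <- as.matrix(tab[, data_cols, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    if (drop_incomplete) {
      bad_rows <- unique(which(is.na(vals), arr.ind = TRUE)[, 1L])
      warning("dropping ", length(bad_rows),
              " probe(s) with missing values")
      vals <- vals[-bad_rows, , drop = FALSE]
      tab <- tab[-bad_rows, , drop = FALSE]
      if (!is.null(sym)) sym <- sym[-bad_rows]
    } else {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("non-numeric or missing expression value at probe '",
           tab$probe_id[bad[1L]], "', sample '", colnames(vals)[bad[2L]],
           "'")
    }
  }
  rownames(vals) <- tab$probe_id

  meta <- utils::read.csv(metadata_csv, colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata CSV must have columns 'sample_id' and 'group'")
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  grp <- stats::setNames(meta$group, meta$sample_id)[colnames(vals)]
  if (is.null(sym)) sym <- tab$probe_id
  expression_matrix(vals, biotype = tab$biotype, group = grp,
                    case_label = case_label, control_label = control_label,
                    gene_symbol = sym)
}

#' Write an expression matrix and metadata to disk
#'
#' Inverse of [read_expression()]; numeric values are written with 6
#' significant digits.
#'
#' @param x a `cnc_expression` object.
#' @param expression_tsv,metadata_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(x, expression_tsv, metadata_csv) {
  stopifnot(inherits(x, "cnc_expression"))
  out <- data.frame(probe_id = rownames(x$values),
                    biotype = unname(x$biotype),
                    gene_symbol = unname(x$gene_symbol),
                    signif(x$values, 6L),
                    check.names = FALSE)
  utils::write.table(out, expression_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(data.frame(sample_id = colnames(x$values),
                              group = unname(x$group)),
                   metadata_csv, row.names = FALSE, quote = FALSE)
  invisible(c(expression_tsv, metadata_csv))
}

#' Read genomic loci from a BED file
#'
#' BED3+ with a name column (column 4 = probe id). Coordinates are 0-based,
#' half-open per the BED standard. Strand is taken from column 6 when
#' present, otherwise `"unknown"`.
#'
#' @param path BED file path.
#' @return data.frame with columns `probe_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(probe_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4L))
    stop("BED line ", which(n_fields < 4L)[1L],
         ": need at least 4 fields (chrom, start, end, name)")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  name <- vapply(fields, `[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED line ", bad[1L], ": invalid interval (need 0 <= start < end)")
  strand <- ifelse(n_fields >= 6L,
                   vapply(fields, function(f) f[min(6L, length(f))], ""),
                   "unknown")
  strand[!strand %in% c("+", "-")] <- "unknown"
  data.frame(probe_id = name, chrom = chrom, start = start, end = end,
             strand = strand)
}

#' Write genomic loci to a BED file
#' @param loci data.frame as returned by [read_bed()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(loci, path) {
  strand <- ifelse(loci$strand %in% c("+", "-"), loci$strand, ".")
  writeLines(paste(loci$chrom, format(loci$start, scientific = FALSE,
                                      trim = TRUE),
                   format(loci$end, scientific = FALSE, trim = TRUE),
                   loci$probe_id, 0L, strand, sep = "\t"), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `set_id TAB description TAB member1 TAB member2 ...`.
#' Duplicate members within a line are collapsed with a warning.
#'
#' @param path GMT file path.
#' @return named list of gene sets; each element is a list with `set_id`,
#'   `description`, `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], ": need set_id, description and >= 1 member")
  sets <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT set '", f[1L], "': duplicate member(s) collapsed")
      members <- unique(members)
    }
    list(set_id = f[1L], description = f[2L], members = members)
  })
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  sets
}

#' Export a coexpression network for Cytoscape and friends
#'
#' SIF uses the dialect `lncID<TAB>coexp<TAB>mrnaID`, one edge per line.
#' GraphML (via igraph) carries node attributes (`biotype`, `direction`,
#' `degree`) and edge attributes (`pcc`, `p`).
#'
#' @param network a `cnc_network` object from [build_cnc()].
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  stopifnot(inherits(network, "cnc_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(network$edges))
      paste(network$edges$lnc_id, "coexp", network$edges$mrna_id,
            sep = "\t") else character(0)
    writeLines(lines, path)
  } else {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a CNC network to an igraph graph
#' @param network a `cnc_network` object.
#' @return an undirected bipartite [igraph::graph] with node attributes
#'   `biotype`, `direction`, `degree` and edge attributes `pcc`, `p`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cnc_network"))
  nodes <- network$nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges$lnc_id, to = network$edges$mrna_id,
               pcc = network$edges$pcc, p = network$edges$p_value),
    directed = FALSE,
    vertices = data.frame(name = nodes$id, biotype = nodes$biotype,
                          direction = nodes$direction, degree = nodes$degree))
  g
}
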