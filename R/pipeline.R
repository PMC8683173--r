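#' Assemble a pipeline configuration
#'
#' Collects the input paths, the screening/network thresholds and the mode
#' flags of a full analysis run. Thresholds default to the conventional
#' values of the CNC literature: |FC| >= 1.5 with raw P < 0.05 for
#' differential expression, |PCC| > 0.7 with P < 0.05 for edges, degree >
#' 60 for hubs, a 300 kb cis window, top 30 edges, and P < 0.05 for
#' enrichment.
#'
#' @param expression_tsv,metadata_csv,bed,gmt,qpcr_csv input paths
#'   (`gmt` and `qpcr_csv` may be `NULL`; those stages are then skipped).
#' @param fc_threshold,p_de,pcc_threshold,p_edge,min_degree,window_bp,top_k,p_enrich
#'   stage thresholds.
#' @param correlation_samples `"pooled"` or `"case"`/`"control"`.
#' @param qpcr_method `"t"` or `"mann-whitney"`.
#' @param case_label,control_label group labels (defaults `"PDC"`, `"BC"`).
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed covers any downstream resampling).
#' @return list of class `cnc_pipeline_config`.
#' @export
pipeline_config <- function(expression_tsv, metadata_csv, bed,
                            gmt = NULL, qpcr_csv = NULL,
                            fc_threshold = 1.5, p_de = 0.05,
                            pcc_threshold = 0.7, p_edge = 0.05,
                            min_degree = 60, window_bp = 300000,
                            top_k = 30, p_enrich = 0.05,
                            correlation_samples = "pooled",
                            qpcr_method = "t",
                            case_label = "PDC", control_label = "BC",
                            seed = 1L) {
  thresholds <- c(fc_threshold = fc_threshold, p_de = p_de,
                  pcc_threshold = pcc_threshold, p_edge = p_edge,
                  min_degree = min_degree, window_bp = window_bp,
                  top_k = top_k, p_enrich = p_enrich)
  if (any(thresholds <= 0))
    stop("all thresholds must be positive; offending: ",
         paste(names(thresholds)[thresholds <= 0], collapse = ", "))
  structure(list(expression_tsv = expression_tsv,
                 metadata_csv = metadata_csv, bed = bed, gmt = gmt,
                 qpcr_csv = qpcr_csv,
                 fc_threshold = fc_threshold, p_de = p_de,
                 pcc_threshold = pcc_threshold, p_edge = p_edge,
                 min_degree = min_degree, window_bp = window_bp,
                 top_k = top_k, p_enrich = p_enrich,
                 correlation_samples = correlation_samples,
                 qpcr_method = qpcr_method,
                 case_label = case_label, control_label = control_label,
                 seed = as.integer(seed)),
            class = "cnc_pipeline_config")
}

#' Run the full lncRNA-target analysis chain
#'
#' Stages: differential expression (moderated t + fold-change filter) ->
#' CNC network -> hubs and top-k edges -> cis-window intersection ->
#' direction-split enrichment -> qPCR validation, writing every stage's
#' table to `out_dir` along with SIF/GraphML network exports, figures and a
#' JSON run manifest (config, stage row counts, wall time). Re-running with
#' identical inputs and config reproduces identical tables. All referenced
#' input files are validated before any stage executes; a stage failure
#' aborts with the stage name and leaves `complete: false` in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param figures write PNG figures (default TRUE; tables are unaffected).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, figures = TRUE) {
  stopifnot(inherits(config, "cnc_pipeline_config"))
  inputs <- c(config$expression_tsv, config$metadata_csv, config$bed,
              config$gmt, config$qpcr_csv)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  counts <- list()
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest <- function(complete) {
    jsonlite::write_json(
      list(config = config[setdiff(names(config), NULL)],
           seed = config$seed, stage_counts = counts,
           wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
           complete = complete),
      manifest_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      write_manifest(FALSE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(tab, file) {
    utils::write.csv(tab, file.path(out_dir, file), row.names = FALSE)
    counts[[sub("\\.csv$", "", file)]] <<- nrow(tab)
  }

  x <- stage("read_inputs", read_expression(
    config$expression_tsv, config$metadata_csv,
    case_label = config$case_label, control_label = config$control_label))
  loci <- stage("read_inputs", read_bed(config$bed))

  de <- stage("diffexpr", moderated_t_test(
    x, fc_threshold = config$fc_threshold, p_threshold = config$p_de))
  emit(de, "de_results.csv")
  message("diffexpr: ", sum(de$is_de), " / ", nrow(de), " probes pass |FC| >= ",
          config$fc_threshold, " & P < ", config$p_de,
          " (", sum(de$is_de & de$biotype == "lncRNA"), " lncRNA, ",
          sum(de$is_de & de$biotype == "mRNA"), " mRNA)")

  net <- stage("coexpression", build_cnc(
    x, de, pcc_threshold = config$pcc_threshold,
    p_threshold = config$p_edge, samples = config$correlation_samples))
  emit(net$edges, "network_edges.csv")
  hubs <- degree_filter(net, config$min_degree)
  nodes <- net$nodes
  nodes$is_hub <- nodes$id %in% hubs$id
  emit(nodes, "network_nodes.csv")
  emit(top_edges(net, config$top_k), "top_edges.csv")
  stage("coexpression", {
    write_network(net, file.path(out_dir, "network.sif"), "sif")
    write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  })
  message("coexpression: ", nrow(net$edges), " edges, ",
          nrow(nodes), " nodes, ", nrow(hubs), " hubs (degree > ",
          config$min_degree, ")")

  cis <- stage("cis_targets", {
    de_lnc <- de$probe_id[de$is_de & de$biotype == "lncRNA"]
    de_mrna <- de$probe_id[de$is_de & de$biotype == "mRNA"]
    absent <- setdiff(c(de_lnc, de_mrna), loci$probe_id)
    if (length(absent))
      message("cis_targets: no locus for ", length(absent),
              " DE probe(s); skipped")
    find_cis_pairs(loci[loci$probe_id %in% de_lnc, , drop = FALSE],
                   loci[loci$probe_id %in% de_mrna, , drop = FALSE],
                   window_bp = config$window_bp)
  })
  emit(cis, "cis_pairs.csv")
  cis_coexp <- stage("cis_targets", intersect_cis_coexpressed(cis, net))
  emit(cis_coexp, "cis_coexpressed.csv")
  emit(cis_summary(cis_coexp), "cis_summary.csv")
  message("cis_targets: ", nrow(cis), " pairs within ", config$window_bp,
          " bp; ", nrow(cis_coexp), " also coexpressed")

  enr <- NULL
  if (!is.null(config$gmt)) enr <- stage("enrichment", {
    sets <- read_gmt(config$gmt)
    sym <- x$gene_symbol
    universe <- unique(unname(sym[x$biotype == "mRNA"]))
    dirs <- split_by_direction(de[de$biotype == "mRNA", , drop = FALSE],
                               ids = unname(sym[de$biotype == "mRNA"]))
    up <- ora(dirs$up, universe, sets, config$p_enrich)
    down <- ora(dirs$down, universe, sets, config$p_enrich)
    emit(up, "enrichment_up.csv")
    emit(down, "enrichment_down.csv")
    message("enrichment: ", sum(up$significant), " sets (up), ",
            sum(down$significant), " sets (down) at P < ", config$p_enrich)
    list(up = up, down = down)
  })

  qp <- NULL
  if (!is.null(config$qpcr_csv)) qp <- stage("qpcr", {
    rec <- read_qpcr(config$qpcr_csv)
    rel <- delta_delta_ct(rec, control_label = config$control_label)
    cmp <- group_compare(rel, method = config$qpcr_method,
                         case_label = config$case_label,
                         control_label = config$control_label)
    emit(rel, "qpcr_relative_expression.csv")
    emit(cmp, "qpcr_comparison.csv")
    arr_dir <- stats::setNames(sign(de$log2fc), de$probe_id)
    shared <- intersect(cmp$gene_id, names(arr_dir))
    conc <- if (length(shared))
      concordance(stats::setNames(cmp$direction, cmp$gene_id),
                  arr_dir, shared) else NULL
    if (!is.null(conc)) {
      fold_cmp <- data.frame(
        gene_id = shared,
        qpcr_fold = cmp$mean_fold_case[match(shared, cmp$gene_id)] /
          cmp$mean_fold_control[match(shared, cmp$gene_id)],
        array_fc = de$fc[match(shared, de$probe_id)])
      emit(fold_cmp, "qpcr_vs_array.csv")
      emit(conc$table, "qpcr_concordance.csv")
      message("qpcr: direction concordance ",
              format(100 * conc$fraction), "% over ", length(shared),
              " gene(s)")
    }
    list(relative = rel, comparison = cmp, concordance = conc)
  })

  if (figures) stage("figures", {
    ggplot2::ggsave(file.path(out_dir, "volcano.png"),
                    plot_volcano(de, config$fc_threshold, config$p_de),
                    width = 6, height = 5, dpi = 150)
    if (!is.null(enr) && any(enr$up$significant))
      ggplot2::ggsave(file.path(out_dir, "enrichment_up.png"),
                      plot_enrichment(enr$up), width = 6, height = 5,
                      dpi = 150)
    if (!is.null(enr) && any(enr$down$significant))
      ggplot2::ggsave(file.path(out_dir, "enrichment_down.png"),
                      plot_enrichment(enr$down), width = 6, height = 5,
                      dpi = 150)
    if (!is.null(qp))
      ggplot2::ggsave(file.path(out_dir, "qpcr_folds.png"),
                      plot_qpcr(qp$relative, qp$comparison),
                      width = 6, height = 4, dpi = 150)
  })

  write_manifest(TRUE)
  invisible(list(expression = x, de = de, network = net, hubs = hubs,
                 cis = cis, cis_coexpressed = cis_coexp,
                 enrichment = enr, qpcr = qp,
                 manifest = manifest_path, out_dir = out_dir))
}

#' Write a complete synthetic input bundle
#'
#' Generates expression, metadata, loci, gene sets, qPCR Ct values and the
#' ground-truth tables for one seeded synthetic dataset, as the files
#' [run_pipeline()] consumes. qPCR targets default to both members of each
#' planted cis pair (capped at 5 pairs); gene sets comprise one set per
#' direction enriched in planted DE mRNAs plus random background sets.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file paths (named as the
#'   [pipeline_config()] arguments expect) and the `truth` tables.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "cnc_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_expression(config)
  ann <- generate_annotation(config, gen$truth)
  paths <- list(expression_tsv = file.path(dir, "expression.tsv"),
                metadata_csv = file.path(dir, "samples.csv"),
                bed = file.path(dir, "probes.bed"),
                gmt = file.path(dir, "gene_sets.gmt"),
                qpcr_csv = file.path(dir, "qpcr.csv"))
  write_expression(gen$expression, paths$expression_tsv, paths$metadata_csv)
  write_bed(ann, paths$bed)

  # ground truth for recovery benchmarking
  utils::write.csv(gen$truth$de, file.path(dir, "truth_de.csv"),
                   row.names = FALSE)
  utils::write.csv(gen$truth$linked_pairs,
                   file.path(dir, "truth_pairs.csv"), row.names = FALSE)

  set.seed(config$seed + 3L)
  mrna_ids <- .probe_ids(config)[config$n_lnc + seq_len(config$n_mrna)]
  de_mrna <- gen$truth$de[gen$truth$de$biotype == "mRNA", , drop = FALSE]
  sets <- character()
  if (nrow(de_mrna)) {
    for (dname in c("up", "down")) {
      ids <- de_mrna$probe_id[de_mrna$direction == (if (dname == "up") 1 else -1)]
      if (length(ids) >= 2L)
        sets <- c(sets, paste(c(paste0("PLANTED_", toupper(dname)),
                                paste("planted", dname, "set"), ids),
                              collapse = "\t"))
    }
  }
  for (i in 1:8) {
    members <- sample(mrna_ids, min(25L, length(mrna_ids)))
    sets <- c(sets, paste(c(sprintf("RANDOM_%02d", i), "random background set",
                            members), collapse = "\t"))
  }
  writeLines(sets, paths$gmt)

  cis <- gen$truth$linked_pairs[gen$truth$linked_pairs$is_cis, , drop = FALSE]
  targets <- if (nrow(cis)) {
    utils::head(c(rbind(cis$lnc_id, cis$mrna_id)), 10L)
  } else utils::head(gen$truth$de$probe_id, 5L)
  if (length(targets)) {
    qp <- generate_qpcr(config, gen$truth, targets)
    utils::write.csv(qp, paths$qpcr_csv, row.names = FALSE, quote = FALSE)
  } else paths$qpcr_csv <- NULL

  invisible(c(paths, list(truth = gen$truth, dir = dir)))
}
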