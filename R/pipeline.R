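#' Pipeline run configuration
#'
#' Bundles the input file paths and the per-stage parameter blocks for
#' [run_all()]. All referenced files must exist when the config is built.
#'
#' @param counts path to the long STARR count table.
#' @param tss path to the TSS table (one row per promoter).
#' @param de path to the differential-expression table.
#' @param tf_peaks named character vector of per-TF peak BED paths (the key
#'   TFs whose composite peaks define ISGF3-like binding).
#' @param isre_sites path to the ISRE motif-site BED (name column = TF,
#'   narrowPeak p-value column or none).
#' @param tads path to the TAD BED.
#' @param chrom_sizes path to a two-column chrom.sizes file.
#' @param out_dir output directory for stage tables and the summary.
#' @param starr,de_cfg,motif,clustering,enrichment stage parameter blocks
#'   ([starr_config()], [de_config()], [motif_config()],
#'   [cluster_config()]; `enrichment` is a list with `n_shuffles` and
#'   `seed` handed to [enrichment_config()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, tss, de, tf_peaks, isre_sites, tads,
                       chrom_sizes, out_dir,
                       starr = starr_config(), de_cfg = de_config(),
                       motif = motif_config(), clustering = cluster_config(),
                       enrichment = list(n_shuffles = 100L, seed = 1L)) {
  paths <- c(counts = counts, tss = tss, de = de, tf_peaks,
             isre_sites = isre_sites, tads = tads, chrom_sizes = chrom_sizes)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("missing input file(s): ", paste(absent, collapse = ", "))
  structure(list(counts = counts, tss = tss, de = de, tf_peaks = tf_peaks,
                 isre_sites = isre_sites, tads = tads,
                 chrom_sizes = chrom_sizes, out_dir = out_dir,
                 starr = starr, de_cfg = de_cfg, motif = motif,
                 clustering = clustering, enrichment = enrichment),
            class = "run_config")
}

#' @keywords internal
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full Epromoter pipeline
#'
#' Sequences the stages in dependency order: promoter activity
#' quantification and Epromoter calling; gene classification and
#' response-set assignment; composite-peak construction and nearest-peak
#' annotation of induced genes; ISRE site counting; TSS clustering with
#' typing, TAD status and Epromoter-like prediction; and positional
#' enrichment of composite peaks in promoter windows against the shuffle
#' null. Writes one TSV per stage plus `summary.json` into `out_dir` and
#' logs every threshold used. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress the threshold log (default FALSE).
#' @return list with `activity`, `gene_sets`, `peak_annotation`,
#'   `isre_counts`, `clusters`, `enrichment` and `summary`.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  tss <- .stage("core_io", read_tss(config$tss))
  if (is.null(tss$promoter_id)) tss$promoter_id <- tss$gene_id
  sizes <- .stage("core_io", read_chrom_sizes(config$chrom_sizes))
  tads <- .stage("core_io", read_bed(config$tads))

  # --- activity ---------------------------------------------------------
  counts <- .stage("starr_activity", read_count_table(config$counts))
  windows <- capture_windows(tss, config$starr$design)
  activity <- .stage("starr_activity",
                     quantify_activity(counts, windows, config$starr))
  tau <- attr(activity, "tau")
  say(sprintf("activity thresholds (inflection): ns=%.4g stim=%.4g; ",
              tau[1], tau[2]),
      sprintf("input FPKM floor %.3g, induction ratio > %.3g",
              config$starr$fpkm_min_input, config$starr$induced_ratio))

  # --- expression classes -----------------------------------------------
  de <- .stage("expression_classes", read_de_table(config$de))
  gene_classes <- .stage("expression_classes", classify_de(de, config$de_cfg))
  say(sprintf("DE thresholds: |log2FC| > %.3g, p < %.3g",
              config$de_cfg$lfc_min, config$de_cfg$padj_max))
  pmap <- tss[, c("promoter_id", "gene_id")]
  sets <- .stage("expression_classes",
                 assign_promoter_sets(gene_classes, activity, pmap))

  # --- binding analysis -------------------------------------------------
  peak_sets <- .stage("binding_analysis",
                      lapply(config$tf_peaks, read_bed))
  comp <- .stage("binding_analysis", composite_peaks(peak_sets))
  flank <- config$starr$design$flank
  induced_only <- sets$genes$gene_id[sets$genes$induced_gene_only &
                                       !sets$genes$induced_gene_and_epromoter]
  gene_tss <- tss[!duplicated(tss$gene_id), ]
  annot <- .stage("binding_analysis", nearest_peak_category(
    gene_tss[gene_tss$gene_id %in% induced_only, ], comp, gene_tss, flank))

  # --- ISRE sites -------------------------------------------------------
  sites <- .stage("isre_sites", read_bed(config$isre_sites))
  if (is.null(sites$name)) stop("pipeline stage 'isre_sites' failed: ",
                                "site BED needs a name column (TF)")
  site_sets <- split(sites, sites$name)
  isre <- .stage("isre_sites",
                 count_isre(capture_windows(tss, config$motif$design),
                            site_sets, config$motif))
  say(sprintf("ISRE high-confidence tier: p < %.3g", config$motif$high_conf_p))

  # --- clustering -------------------------------------------------------
  loci <- sets$promoters[sets$promoters$set_label != "other", ]
  loci <- merge(loci, tss[, c("promoter_id", "chrom", "tss")],
                by = "promoter_id", sort = FALSE)
  loci$constitutive_epromoter <-
    sets$genes$constitutive_epromoter[match(loci$gene_id, sets$genes$gene_id)]
  clustering <- .stage("cluster_calling",
                       cluster_tss(loci, config$clustering))
  bmat <- .stage("cluster_calling",
                 binding_matrix(flank_windows(tss, flank), peak_sets))
  cluster_table <- .stage("cluster_calling", if (nrow(clustering$clusters))
    summarize_clusters(clustering, tads, bmat) else NULL)
  say(sprintf("cluster linkage: TSS distance %s %d bp, >= %d members",
              if (config$clustering$strict_lt) "<" else "<=",
              config$clustering$max_gap, config$clustering$min_members))

  # --- enrichment -------------------------------------------------------
  ecfg <- enrichment_config(config$enrichment$n_shuffles,
                            config$enrichment$seed, sizes)
  enr <- .stage("stats_tests",
                shuffle_enrichment(comp, flank_windows(gene_tss, flank), ecfg))

  # --- summary ----------------------------------------------------------
  lab_counts_prom <- table(factor(sets$promoters$set_label,
                                  c("induced_gene_only",
                                    "induced_gene_and_epromoter",
                                    "induced_epromoter_only", "other")))
  gene_lab <- c(induced_gene_only = sum(sets$genes$induced_gene_only),
                induced_gene_and_epromoter =
                  sum(sets$genes$induced_gene_and_epromoter),
                induced_epromoter_only =
                  sum(sets$genes$induced_epromoter_only))
  summary <- list(
    n_promoters = nrow(activity),
    n_removed_input_filter = sum(activity$removed),
    tau = as.list(tau),
    n_epromoters_ns = sum(activity$epromoter_ns, na.rm = TRUE),
    n_epromoters_stim = sum(activity$epromoter_stim, na.rm = TRUE),
    n_induced_epromoters = sum(activity$induced_epromoter, na.rm = TRUE),
    n_repressed_epromoters = sum(activity$repressed_epromoter, na.rm = TRUE),
    n_constitutive_epromoters = sum(activity$constitutive_epromoter,
                                    na.rm = TRUE),
    de_classes = as.list(table(gene_classes$de_class)),
    promoter_set_counts = as.list(lab_counts_prom),
    gene_set_counts = as.list(gene_lab),
    peak_categories = summarize_categories(
      table(factor(annot$category, c("same_promoter", "another_promoter",
                                     "intergenic", "unannotated")))),
    isre_class_all = summarize_categories(table(factor(isre$class_all,
                                                       c("0", "1", ">=2")))),
    isre_class_highconf = summarize_categories(
      table(factor(isre$class_highconf, c("0", "1", ">=2")))),
    n_clusters = if (is.null(cluster_table)) 0L else nrow(cluster_table),
    n_clusters_with_epromoter = if (is.null(cluster_table)) 0L else
      sum(cluster_table$has_epromoter),
    n_epromoter_like_clusters = if (is.null(cluster_table)) 0L else
      sum(cluster_table$epromoter_like),
    cluster_tad_status = if (is.null(cluster_table)) list() else
      as.list(table(factor(cluster_table$tad_status, c("Y", "N", "O")))),
    enrichment = list(observed = enr$observed, shuffle_mean = enr$shuffle_mean,
                      shuffle_sd = enr$shuffle_sd, p_value = enr$p_value,
                      method = enr$method))

  write_table(activity, file.path(config$out_dir, "activity.tsv"))
  write_table(sets$promoters, file.path(config$out_dir, "promoter_sets.tsv"))
  write_table(sets$genes, file.path(config$out_dir, "gene_sets.tsv"))
  write_table(annot, file.path(config$out_dir, "peak_annotation.tsv"))
  write_table(isre, file.path(config$out_dir, "isre_counts.tsv"))
  if (!is.null(cluster_table))
    write_table(cluster_table, file.path(config$out_dir, "clusters.tsv"))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(activity = activity, gene_sets = sets, peak_annotation = annot,
       isre_counts = isre, clustering = clustering, clusters = cluster_table,
       enrichment = enr, summary = summary)
}

#' Category counts with percentages
#'
#' @param counts named integer vector (or table) of category counts;
#'   must contain at least one observation.
#' @return list of per-category lists with `count` and `percent`
#'   (2 decimal places); percentages sum to 100 within 0.1.
#' @export
summarize_categories <- function(counts) {
  counts <- unlist(as.list(counts))
  if (length(counts) == 0L || sum(counts) == 0L)
    stop("empty category table")
  pct <- round(100 * counts / sum(counts), 2)
  out <- lapply(seq_along(counts), function(i)
    list(count = unname(counts[i]), percent = unname(pct[i])))
  names(out) <- names(counts)
  out
}
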