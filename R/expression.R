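#' Differential-expression thresholds
#'
#' @param lfc_min log2 fold-change threshold, strict (default 1).
#' @param padj_max p-value ceiling, strict (default 0.001).
#' @param p_is_adjusted whether the p column is multiple-testing adjusted
#'   (default TRUE; the LPS preset uses raw p < 0.01).
#' @return list of class `de_config`.
#' @export
de_config <- function(lfc_min = 1.0, padj_max = 0.001, p_is_adjusted = TRUE) {
  stopifnot(lfc_min > 0, padj_max > 0, padj_max < 1)
  structure(list(lfc_min = lfc_min, padj_max = padj_max,
                 p_is_adjusted = p_is_adjusted),
            class = "de_config")
}

#' Classify genes from a differential-expression table
#'
#' A gene is induced when `log2fc > lfc_min` and `padj < padj_max` (both
#' strict), repressed under the mirrored rule, otherwise unchanged. Genes
#' with a missing p-value are dropped with a warning.
#'
#' @param de_table data.frame with `gene_id`, `log2fc`, `padj`.
#' @param config a [de_config()].
#' @return data.frame with `gene_id` and `de_class` in
#'   `{induced, repressed, unchanged}`.
#' @export
classify_de <- function(de_table, config = de_config()) {
  need <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(need, names(de_table))
  if (length(missing))
    stop("DE table lacks column(s): ", paste(missing, collapse = ", "))
  drop <- is.na(de_table$padj)
  if (any(drop)) {
    warning(sum(drop), " gene(s) dropped: missing p-value")
    de_table <- de_table[!drop, ]
  }
  cls <- ifelse(de_table$log2fc > config$lfc_min &
                  de_table$padj < config$padj_max, "induced",
                ifelse(de_table$log2fc < -config$lfc_min &
                         de_table$padj < config$padj_max, "repressed",
                       "unchanged"))
  data.frame(gene_id = de_table$gene_id, de_class = cls,
             stringsAsFactors = FALSE)
}

#' Assign promoters and genes to response-locus sets
#'
#' Combines gene induction classes with induced-Epromoter calls into the
#' three response-locus sets: `induced_gene_only` (induced gene, promoter
#' without induced Epromoter activity), `induced_gene_and_epromoter`
#' (induced gene with an induced Epromoter promoter), and
#' `induced_epromoter_only` (induced Epromoter on a non-induced gene);
#' everything else is `other`. Labels are assigned per promoter; a gene's
#' labels are the union over its promoters, so genes with alternative
#' promoters can carry several labels. A gene is flagged as associated with
#' a constitutive Epromoter when at least one of its promoters is an
#' Epromoter in both conditions without being induced.
#'
#' @param gene_classes output of [classify_de()].
#' @param activity activity table from [quantify_activity()] (needs
#'   `promoter_id`, `induced_epromoter`, `constitutive_epromoter`,
#'   `removed`).
#' @param promoter_map data.frame mapping `promoter_id` to `gene_id`; every
#'   promoter must map to at least one known gene.
#' @return list with `promoters` (promoter_id, gene_id, set_label) and
#'   `genes` (gene_id, de_class, one logical column per label,
#'   `constitutive_epromoter`).
#' @export
assign_promoter_sets <- function(gene_classes, activity, promoter_map) {
  stopifnot(all(c("promoter_id", "gene_id") %in% names(promoter_map)))
  unknown <- setdiff(promoter_map$gene_id, gene_classes$gene_id)
  if (length(unknown))
    stop("promoter(s) mapped to unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  m <- promoter_map
  m$de_class <- gene_classes$de_class[match(m$gene_id, gene_classes$gene_id)]
  ai <- match(m$promoter_id, activity$promoter_id)
  if (anyNA(ai))
    stop("promoter(s) missing from activity table: ",
         paste(utils::head(m$promoter_id[is.na(ai)], 5), collapse = ", "))
  m$induced_ep <- activity$induced_epromoter[ai] %in% TRUE
  m$constitutive_ep <- activity$constitutive_epromoter[ai] %in% TRUE
  gene_induced <- m$de_class == "induced"
  m$set_label <- ifelse(gene_induced & m$induced_ep, "induced_gene_and_epromoter",
                 ifelse(gene_induced, "induced_gene_only",
                 ifelse(m$induced_ep, "induced_epromoter_only", "other")))
  labels <- c("induced_gene_only", "induced_gene_and_epromoter",
              "induced_epromoter_only")
  genes <- data.frame(gene_id = gene_classes$gene_id,
                      de_class = gene_classes$de_class,
                      stringsAsFactors = FALSE)
  for (lab in labels)
    genes[[lab]] <- genes$gene_id %in% m$gene_id[m$set_label == lab]
  genes$constitutive_epromoter <-
    genes$gene_id %in% m$gene_id[m$constitutive_ep]
  list(promoters = m[, c("promoter_id", "gene_id", "set_label")],
       genes = genes)
}
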