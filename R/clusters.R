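#' Cluster configuration
#'
#' @param max_gap maximum TSS-to-TSS distance in bp for two loci to be
#'   linked (default 100000, inclusive; set `strict_lt = TRUE` for a strict
#'   "closer than" reading).
#' @param min_members minimum loci per reported cluster (default 2).
#' @param strict_lt use `< max_gap` instead of `<= max_gap` (default FALSE).
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(max_gap = 100000L, min_members = 2L,
                           strict_lt = FALSE) {
  stopifnot(max_gap > 0, min_members >= 2)
  structure(list(max_gap = as.integer(max_gap),
                 min_members = as.integer(min_members),
                 strict_lt = isTRUE(strict_lt)),
            class = "cluster_config")
}

#' Single-linkage clustering of TSS positions
#'
#' Two loci are linked when they lie on the same chromosome with TSS
#' distance within `max_gap`; clusters are the connected components of this
#' relation (so members can be transitively linked through intermediate
#' loci) with at least `min_members` loci. Remaining loci are reported as
#' unclustered. Duplicate `(gene_id, tss)` rows are deduplicated with a
#' warning. The result is invariant to input order.
#'
#' @param tss_records TSS data.frame (`gene_id`, `chrom`, `tss`, optional
#'   `promoter_id`).
#' @param config a [cluster_config()].
#' @return list with `members` (tss_records plus `cluster_id`, NA for
#'   unclustered) and `clusters` (cluster_id, chrom, n_members, span_start,
#'   span_end).
#' @export
cluster_tss <- function(tss_records, config = cluster_config()) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss_records)))
  key <- paste(tss_records$gene_id, tss_records$chrom, tss_records$tss)
  if (anyDuplicated(key)) {
    warning("duplicate (gene, tss) rows deduplicated")
    tss_records <- tss_records[!duplicated(key), ]
  }
  ord <- order(tss_records$chrom, tss_records$tss)
  rec <- tss_records[ord, ]
  link <- function(gap) if (config$strict_lt) gap < config$max_gap
                        else gap <= config$max_gap
  # on a line, single linkage = cut sorted positions at large adjacent gaps
  comp <- integer(nrow(rec))
  cid <- 0L
  for (chr in unique(rec$chrom)) {
    idx <- which(rec$chrom == chr)
    gaps <- diff(rec$tss[idx])
    newgrp <- c(TRUE, !link(gaps))
    comp[idx] <- cid + cumsum(newgrp)
    cid <- max(comp[idx])
  }
  # membership is counted on distinct genes: alternative promoters of one
  # gene contribute their TSSs to linkage but do not make a cluster alone
  size <- vapply(split(rec$gene_id, comp), function(g) length(unique(g)),
                 integer(1))
  keep <- as.integer(names(size)[size >= config$min_members])
  cluster_id <- ifelse(comp %in% keep, match(comp, sort(keep)), NA_integer_)
  rec$cluster_id <- cluster_id
  members <- rec[order(ord), ]            # restore input order
  rownames(members) <- NULL
  cl <- members[!is.na(members$cluster_id), ]
  clusters <- if (nrow(cl)) {
    agg <- do.call(rbind, lapply(split(cl, cl$cluster_id), function(x)
      data.frame(cluster_id = x$cluster_id[1], chrom = x$chrom[1],
                 n_members = nrow(x), span_start = min(x$tss),
                 span_end = max(x$tss), stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(cluster_id = integer(), chrom = character(),
               n_members = integer(), span_start = integer(),
               span_end = integer(), stringsAsFactors = FALSE)
  }
  list(members = members, clusters = clusters)
}

#' Tally response-set categories within a cluster
#'
#' @param member_labels character vector of set labels for the cluster's
#'   gene members (values of `set_label` from [assign_promoter_sets()]).
#' @param constitutive logical vector: does the member gene carry a
#'   constitutive Epromoter?
#' @return one-row data.frame with counts `n_induced_only`,
#'   `n_induced_and_ep`, `n_ep_only`, plus `has_epromoter` (any induced
#'   Epromoter member) and `has_constitutive_ep`.
#' @export
type_cluster <- function(member_labels, constitutive = logical(length(member_labels))) {
  known <- c("induced_gene_only", "induced_gene_and_epromoter",
             "induced_epromoter_only")
  if (any(is.na(member_labels)) || any(!member_labels %in% known))
    stop("unlabeled cluster member(s)")
  data.frame(
    n_induced_only = sum(member_labels == "induced_gene_only"),
    n_induced_and_ep = sum(member_labels == "induced_gene_and_epromoter"),
    n_ep_only = sum(member_labels == "induced_epromoter_only"),
    has_epromoter = any(member_labels != "induced_gene_only"),
    has_constitutive_ep = any(constitutive))
}

#' TAD status of a cluster
#'
#' `Y` when every member TSS falls inside the same merged TAD, `O` when at
#' least one member falls outside all TADs (this takes precedence), `N`
#' when members are spread over different TADs.
#'
#' @param member_tss data.frame with `chrom` and `tss` for the cluster's
#'   members.
#' @param tads interval data.frame of TADs; overlapping TADs are merged
#'   first.
#' @return one of `"Y"`, `"N"`, `"O"`.
#' @export
tad_status <- function(member_tss, tads) {
  merged <- merge_intervals(tads)
  hit <- vapply(seq_len(nrow(member_tss)), function(i) {
    j <- which(merged$chrom == member_tss$chrom[i] &
                 merged$start <= member_tss$tss[i] &
                 member_tss$tss[i] < merged$end)
    if (length(j) == 0L) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(hit)) return("O")
  if (length(unique(hit)) == 1L) "Y" else "N"
}

#' Predict an Epromoter-regulated cluster from TF binding
#'
#' A cluster is predicted to be regulated by an Epromoter when exactly one
#' member promoter binds at least one of the key TFs while every other
#' member promoter binds none.
#'
#' @param member_promoters promoter ids of the cluster's members.
#' @param bmat logical binding matrix from [binding_matrix()] (promoters x
#'   TFs).
#' @return TRUE/FALSE.
#' @export
predict_epromoter_like <- function(member_promoters, bmat) {
  missing <- setdiff(member_promoters, rownames(bmat))
  if (length(missing))
    stop("promoter(s) missing from binding matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  n_bound <- rowSums(bmat[member_promoters, , drop = FALSE]) >= 1
  sum(n_bound) == 1L
}

#' Summarize clusters with typing, TAD status and Epromoter-like prediction
#'
#' @param clustering output of [cluster_tss()] where `members` carries a
#'   `set_label` column (and optionally `constitutive_epromoter` and
#'   `promoter_id`).
#' @param tads interval data.frame of TADs, or NULL to skip TAD status.
#' @param bmat binding matrix from [binding_matrix()], or NULL to skip the
#'   Epromoter-like prediction.
#' @return data.frame, one row per cluster, combining [type_cluster()],
#'   [tad_status()] and [predict_epromoter_like()] with member lists.
#' @export
summarize_clusters <- function(clustering, tads = NULL, bmat = NULL) {
  members <- clustering$members
  stopifnot(!is.null(members$set_label))
  cl <- members[!is.na(members$cluster_id), ]
  rows <- lapply(split(cl, cl$cluster_id), function(x) {
    # a gene contributes each promoter's TSS to linkage but counts once
    gx <- x[!duplicated(x$gene_id), ]
    out <- type_cluster(gx$set_label,
                        if (is.null(gx$constitutive_epromoter)) logical(nrow(gx))
                        else gx$constitutive_epromoter)
    out$cluster_id <- x$cluster_id[1]
    out$chrom <- x$chrom[1]
    out$n_members <- nrow(gx)
    out$members <- paste(gx$gene_id, collapse = ",")
    out$tad_status <- if (is.null(tads)) NA_character_
                      else tad_status(x[, c("chrom", "tss")], tads)
    out$epromoter_like <- if (is.null(bmat)) NA else
      predict_epromoter_like(unique(if (is.null(x$promoter_id)) x$gene_id
                                    else x$promoter_id), bmat)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- c("cluster_id", "chrom", "n_members", "members",
            "n_induced_only", "n_induced_and_ep", "n_ep_only",
            "has_epromoter", "has_constitutive_ep", "tad_status",
            "epromoter_like")
  out[, cols]
}
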