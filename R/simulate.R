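#' Synthetic-genome configuration
#'
#' Defaults describe the study conditions the recovery tests run under: a
#' 2,000-gene genome with 40 planted clusters of co-induced genes, STARR
#' activity fold-change 5 for active promoters over a background of 1,
#' planted induction ratio 4, negative-binomial count dispersion 0.2 and 3
#' replicates per condition.
#'
#' @param seed global seed; expanded into per-component substreams so adding
#'   a simulated track does not perturb existing draws.
#' @param n_chroms,chrom_length genome geometry (default 4 x 50 Mb).
#' @param n_genes total genes (default 2000).
#' @param n_clusters planted clusters of co-induced loci (default 40).
#' @param cluster_span bp spanned by a cluster's TSSs (default 80000; must
#'   stay below the clustering `max_gap` so planted members always link).
#' @param frac_induced fraction of background (non-cluster) genes that are
#'   induced, placed isolated from other induced loci (default 0.03).
#' @param frac_epromoter_hubs fraction of clusters regulated through a
#'   single Epromoter hub promoter (default 0.5).
#' @param frac_scattered_ep fraction of background genes given an induced
#'   Epromoter outside any cluster (default 0.005).
#' @param frac_constitutive,frac_repressed_ep fractions of background
#'   promoters with constitutive / repressed Epromoter activity (defaults
#'   0.02 and 0.004).
#' @param frac_multi_promoter fraction of genes with a second alternative
#'   promoter (default 0.05).
#' @param hub_gene_induced_prob probability that a hub's own gene is itself
#'   induced (default 0.6; otherwise the hub is an induced Epromoter on a
#'   non-induced gene).
#' @param activity_fc_active,activity_fc_background planted STARR
#'   fold-changes (defaults 5 and 1).
#' @param induction_ratio_planted stimulated/non-stimulated activity ratio
#'   planted for induced Epromoters (default 4).
#' @param nb_dispersion negative-binomial dispersion of counts (default
#'   0.2; 0 gives deterministic counts equal to their means).
#' @param mu_input mean input-library count per promoter (default 100).
#' @param n_replicates replicates per condition (default 3).
#' @param motif_density_hub,motif_density_background mean ISRE sites per
#'   hub / background promoter (defaults 3 and 0.3).
#' @param tf_peak_at_hub_prob probability that each key TF has a ChIP peak
#'   at a hub promoter (default 0.95).
#' @param de_lfc_mean,de_lfc_sd induced-gene log2 fold-change distribution
#'   (defaults 3 and 1, truncated above 1).
#' @param tad_cover_frac probability that a planted cluster lies within one
#'   TAD (default 0.7; the remainder is split evenly between
#'   different-TADs and outside-any-TAD clusters).
#' @param frac_induced_own_peak fraction of isolated induced genes that
#'   recruit the key TFs at their own promoter (default 0.17); cluster
#'   members are excluded so the planted one-bound-promoter structure of
#'   Epromoter-regulated clusters is preserved.
#' @param tf_names key TFs forming composite peaks (default STAT1, STAT2,
#'   IRF9).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 0L, n_chroms = 4L, chrom_length = 5e7,
                       n_genes = 2000L, n_clusters = 40L,
                       cluster_span = 80000L, frac_induced = 0.03,
                       frac_epromoter_hubs = 0.5, frac_scattered_ep = 0.005,
                       frac_constitutive = 0.02, frac_repressed_ep = 0.004,
                       frac_multi_promoter = 0.05,
                       hub_gene_induced_prob = 0.6,
                       activity_fc_active = 5, activity_fc_background = 1,
                       induction_ratio_planted = 4, nb_dispersion = 0.2,
                       mu_input = 100, n_replicates = 3L,
                       motif_density_hub = 3, motif_density_background = 0.3,
                       tf_peak_at_hub_prob = 0.95,
                       de_lfc_mean = 3, de_lfc_sd = 1,
                       tad_cover_frac = 0.7,
                       frac_induced_own_peak = 0.17,
                       tf_names = c("STAT1", "STAT2", "IRF9")) {
  cfg <- as.list(environment())
  fr <- c(frac_induced, frac_epromoter_hubs, frac_scattered_ep,
          frac_constitutive, frac_repressed_ep, frac_multi_promoter,
          hub_gene_induced_prob, tad_cover_frac, tf_peak_at_hub_prob)
  stopifnot(all(fr >= 0 & fr <= 1), induction_ratio_planted > 1,
            activity_fc_active > 1, nb_dispersion >= 0, n_replicates >= 1)
  structure(cfg, class = "sim_config")
}

# per-component substream seeds derived once from the global seed
#' @keywords internal
.substreams <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("genome", "counts", "de", "tracks"))
}

# Gamma-Poisson hierarchy: latent per-window abundance (Gamma, mean mu,
# dispersion phi) + Poisson counting noise => marginal counts are
# NB(mu, phi) across windows; phi = 0 degenerates to deterministic counts
#' @keywords internal
.rabundance <- function(n, mu, phi) {
  if (phi <= 0) return(rep_len(mu, n))
  stats::rgamma(n, shape = 1 / phi, scale = mu * phi)
}

#' @keywords internal
.rcount <- function(mean_count, phi) {
  if (phi <= 0) return(round(mean_count))
  stats::rpois(length(mean_count), mean_count)
}

#' Simulate a genome with planted clusters and ground truth
#'
#' Places `n_clusters` clusters of 2-5 induced loci within `cluster_span`,
#' each at least 300 kb from any other induced locus so the planted cluster
#' memberships are unambiguous; scatters isolated induced genes and neutral
#' background genes; designates one hub promoter per Epromoter-regulated
#' cluster; assigns constitutive/repressed Epromoter promoters in the
#' background; and draws TADs that cover each cluster with probability
#' `tad_cover_frac` (otherwise the cluster is split across two TADs or left
#' outside any TAD). Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `tss` (TSS table, one row per promoter), `tads`
#'   (interval data.frame), `chrom_sizes` (named vector) and `truth` (list
#'   of `promoters`, `genes`, `clusters` truth tables).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substreams(config$seed)[["genome"]])
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- stats::setNames(rep(as.integer(config$chrom_length),
                                     config$n_chroms), chroms)
  guard <- 300000                      # isolation between induced loci
  sizes <- sample(2:5, config$n_clusters, replace = TRUE)
  n_bg <- config$n_genes - sum(sizes)
  if (n_bg < 0) stop("infeasible geometry: clusters exceed n_genes")
  n_bg_ind <- round(config$frac_induced * n_bg)
  n_scat_ep <- round(config$frac_scattered_ep * n_bg)
  # anchors for clusters, isolated induced genes and scattered induced
  # Epromoters, mutually separated so planted cluster membership is exact
  n_anchor <- config$n_clusters + n_bg_ind + n_scat_ep
  anchors <- data.frame(chrom = character(), pos = numeric())
  tries <- 0
  while (nrow(anchors) < n_anchor) {
    tries <- tries + 1
    if (tries > 50 * n_anchor) stop("infeasible geometry: cannot isolate loci")
    chr <- sample(chroms, 1)
    pos <- stats::runif(1, guard, config$chrom_length - config$cluster_span - guard)
    same <- anchors$pos[anchors$chrom == chr]
    if (all(abs(same - pos) > config$cluster_span + guard))
      anchors <- rbind(anchors, data.frame(chrom = chr, pos = pos))
  }
  cl_anchor <- anchors[seq_len(config$n_clusters), ]
  iso_anchor <- anchors[config$n_clusters + seq_len(n_bg_ind), , drop = FALSE]
  scat_anchor <- anchors[config$n_clusters + n_bg_ind + seq_len(n_scat_ep), ,
                         drop = FALSE]

  genes <- list(); prom <- list(); clusters <- list()
  gid <- 0
  add_gene <- function(chrom, tss, de_class, cluster_id) {
    gid <<- gid + 1
    g <- sprintf("G%04d", gid)
    genes[[length(genes) + 1]] <<- data.frame(
      gene_id = g, chrom = chrom, tss = as.integer(round(tss)),
      strand = sample(c("+", "-"), 1), de_class = de_class,
      cluster_id = cluster_id, stringsAsFactors = FALSE)
    g
  }
  hub_of <- character(config$n_clusters)
  ep_like <- stats::runif(config$n_clusters) < config$frac_epromoter_hubs
  for (ci in seq_len(config$n_clusters)) {
    k <- sizes[ci]
    offs <- sort(stats::runif(k, 0, config$cluster_span))
    member_ids <- character(k)
    for (j in seq_len(k)) {
      induced <- TRUE
      if (ep_like[ci] && j == 1)       # hub gene may itself be non-induced
        induced <- stats::runif(1) < config$hub_gene_induced_prob
      member_ids[j] <- add_gene(cl_anchor$chrom[ci], cl_anchor$pos[ci] + offs[j],
                                if (induced) "induced" else "unchanged", ci)
    }
    if (ep_like[ci]) hub_of[ci] <- member_ids[1]
    clusters[[ci]] <- data.frame(cluster_id = ci, chrom = cl_anchor$chrom[ci],
                                 members = paste(member_ids, collapse = ","),
                                 epromoter_like_truth = ep_like[ci],
                                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(iso_anchor)))
    add_gene(iso_anchor$chrom[i], iso_anchor$pos[i], "induced", NA)
  scat_genes <- vapply(seq_len(nrow(scat_anchor)), function(i)
    add_gene(scat_anchor$chrom[i], scat_anchor$pos[i], "unchanged", NA),
    character(1))
  n_rest <- config$n_genes - gid
  n_repressed <- round(0.03 * n_rest)  # repressed genes, not clustered
  for (i in seq_len(n_rest)) {
    repeat {                           # background genes keep clear of induced loci
      chr <- sample(chroms, 1)
      pos <- stats::runif(1, 1000, config$chrom_length - 1000)
      same <- anchors$pos[anchors$chrom == chr]
      if (all(abs(same - pos) > config$cluster_span + guard)) break
    }
    add_gene(chr, pos, if (i <= n_repressed) "repressed" else "unchanged", NA)
  }
  genes <- do.call(rbind, genes)

  # promoters: one per gene, a second alternative promoter for a fraction
  promoters <- data.frame(promoter_id = paste0(genes$gene_id, "_P1"),
                          gene_id = genes$gene_id, chrom = genes$chrom,
                          tss = genes$tss, strand = genes$strand,
                          stringsAsFactors = FALSE)
  alt <- which(stats::runif(nrow(genes)) < config$frac_multi_promoter)
  if (length(alt)) {
    shift <- sample(c(-1, 1), length(alt), replace = TRUE) *
      round(stats::runif(length(alt), 2000, 8000))
    promoters <- rbind(promoters, data.frame(
      promoter_id = paste0(genes$gene_id[alt], "_P2"),
      gene_id = genes$gene_id[alt], chrom = genes$chrom[alt],
      tss = pmax(1000L, genes$tss[alt] + as.integer(shift)),
      strand = genes$strand[alt], stringsAsFactors = FALSE))
  }
  # Epromoter truth at the promoter level
  promoters$is_hub <- promoters$promoter_id %in% paste0(hub_of[nzchar(hub_of)], "_P1")
  promoters$is_induced_epromoter <- promoters$is_hub |
    promoters$promoter_id %in% paste0(scat_genes, "_P1")
  bg_first <- promoters$gene_id %in%
    setdiff(genes$gene_id[is.na(genes$cluster_id) & genes$de_class == "unchanged"],
            scat_genes) &
    grepl("_P1$", promoters$promoter_id)
  u <- stats::runif(nrow(promoters))
  promoters$is_repressed_epromoter <- bg_first &
    u < config$frac_repressed_ep
  promoters$is_constitutive <- bg_first & !promoters$is_repressed_epromoter &
    u >= config$frac_repressed_ep &
    u < config$frac_repressed_ep + config$frac_constitutive
  promoters$is_epromoter <- promoters$is_induced_epromoter |
    promoters$is_repressed_epromoter | promoters$is_constitutive

  # TADs: one covering TAD (Y), a split pair (N) or none (O) per cluster
  tad_rows <- list(); tad_truth <- character(config$n_clusters)
  for (ci in seq_len(config$n_clusters)) {
    m <- genes[genes$cluster_id %in% ci, ]
    lo <- min(m$tss); hi <- max(m$tss)
    u <- stats::runif(1)
    if (u < config$tad_cover_frac) {
      tad_truth[ci] <- "Y"
      tad_rows[[length(tad_rows) + 1]] <- data.frame(
        chrom = m$chrom[1], start = max(0, lo - 20000), end = hi + 20000)
    } else if (u < config$tad_cover_frac + (1 - config$tad_cover_frac) / 2 &&
               nrow(m) >= 2) {
      tad_truth[ci] <- "N"
      cut <- (m$tss[order(m$tss)][1] + sort(m$tss)[2]) %/% 2
      tad_rows[[length(tad_rows) + 1]] <- data.frame(
        chrom = m$chrom[1], start = max(0, lo - 20000), end = cut)
      tad_rows[[length(tad_rows) + 1]] <- data.frame(
        chrom = m$chrom[1], start = cut + 10, end = hi + 20000)
    } else {
      tad_truth[ci] <- "O"
    }
  }
  tads <- if (length(tad_rows)) do.call(rbind, tad_rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  tads$start <- as.integer(tads$start); tads$end <- as.integer(tads$end)

  clusters <- do.call(rbind, clusters)
  clusters$tad_status_truth <- tad_truth
  tss <- promoters[, c("gene_id", "chrom", "tss", "strand", "promoter_id")]
  list(tss = tss, tads = tads, chrom_sizes = chrom_sizes,
       truth = list(promoters = promoters,
                    genes = genes[, c("gene_id", "de_class", "cluster_id")],
                    clusters = clusters))
}

#' Simulate STARR input and reporter counts
#'
#' Counts follow a Gamma-Poisson hierarchy: each promoter window draws a
#' latent capture abundance (Gamma with mean `mu_input` and dispersion
#' `nb_dispersion`, shared by all libraries of that window, as the same
#' captured pool backs them), and every library is a Poisson sample of that
#' abundance times the planted fold-change — so counts are marginally
#' negative binomial over windows while replicates stay highly
#' reproducible, as in the real assay. Planted fold-changes: background 1,
#' active Epromoters `activity_fc_active`, multiplied by
#' `induction_ratio_planted` in the stimulated condition for induced
#' Epromoters (reversed for repressed Epromoters). Dispersion 0 gives
#' deterministic counts equal to their means.
#'
#' @param genome output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return long count table (see [read_count_table()]) with conditions
#'   `ns` and `stim`.
#' @export
simulate_starr_counts <- function(genome, config = sim_config()) {
  set.seed(.substreams(config$seed)[["counts"]])
  p <- genome$truth$promoters
  fc_ns <- ifelse(p$is_constitutive | p$is_induced_epromoter,
                  config$activity_fc_active,
                  ifelse(p$is_repressed_epromoter,
                         config$activity_fc_active * config$induction_ratio_planted,
                         config$activity_fc_background))
  fc_stim <- ifelse(p$is_induced_epromoter,
                    config$activity_fc_active * config$induction_ratio_planted,
                    ifelse(p$is_repressed_epromoter,
                           config$activity_fc_active,
                           fc_ns))
  # capture abundance varies per promoter window (Gamma, dispersion phi);
  # every library is a Poisson sample of it, so counts are marginally
  # NB(mu, phi) across windows. The input is the captured plasmid pool,
  # sequenced once and reused for every condition/replicate row, as when a
  # single input library backs all transfections.
  phi <- config$nb_dispersion
  abundance <- .rabundance(nrow(p), config$mu_input, phi)
  input_count <- .rcount(abundance, phi)
  rows <- list()
  for (cond in c("ns", "stim")) {
    fc <- if (cond == "ns") fc_ns else fc_stim
    for (r in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        region_id = p$promoter_id, condition = cond, replicate = r,
        library = "input", count = input_count,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        region_id = p$promoter_id, condition = cond, replicate = r,
        library = "starr", count = .rcount(abundance * fc, phi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a differential-expression output table
#'
#' Emulates the OUTPUT of a differential-expression fit (the fit itself is
#' out of scope): truth-induced genes draw `log2fc` from a normal truncated
#' above 1 with `padj < 0.001`; repressed genes mirror this; unchanged
#' genes draw `log2fc` near 0 with `padj >= 0.05`.
#'
#' @param genome output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return data.frame with `gene_id`, `log2fc`, `padj`.
#' @export
simulate_de_table <- function(genome, config = sim_config()) {
  set.seed(.substreams(config$seed)[["de"]])
  g <- genome$truth$genes
  n <- nrow(g)
  trunc_norm <- function(k) {          # rejection sample above 1
    out <- numeric(0)
    while (length(out) < k) {
      x <- stats::rnorm(k, config$de_lfc_mean, config$de_lfc_sd)
      out <- c(out, x[x > 1])
    }
    out[seq_len(k)]
  }
  lfc <- stats::rnorm(n, 0, 0.3)
  padj <- stats::runif(n, 0.05, 1)
  ind <- g$de_class == "induced"; rep_ <- g$de_class == "repressed"
  lfc[ind] <- trunc_norm(sum(ind))
  lfc[rep_] <- -trunc_norm(sum(rep_))
  padj[ind | rep_] <- 10^-stats::runif(sum(ind | rep_), 3.5, 10)
  data.frame(gene_id = g$gene_id, log2fc = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

#' Simulate TF ChIP peaks and ISRE motif-site tracks
#'
#' Hub promoters (and scattered induced Epromoters) receive a peak for each
#' key TF with probability `tf_peak_at_hub_prob`, centered near the TSS,
#' plus at least two high-confidence ISRE sites (`p < 1e-4`); background
#' promoters receive Poisson(`motif_density_background`) weak sites
#' (`p >= 1e-4`). A set of intergenic composite peaks is placed away from
#' all promoter windows.
#'
#' @param genome output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @param n_intergenic_peaks intergenic composite-peak loci (default 50).
#' @return list with `peaks` (named list of per-TF interval data.frames)
#'   and `isre_sites` (interval data.frame with `name` = motif TF and
#'   `p_value`).
#' @export
simulate_tf_tracks <- function(genome, config = sim_config(),
                               n_intergenic_peaks = 50L) {
  set.seed(.substreams(config$seed)[["tracks"]])
  p <- genome$truth$promoters
  gtab <- genome$truth$genes
  iso_induced <- gtab$gene_id[gtab$de_class == "induced" & is.na(gtab$cluster_id)]
  own_peak <- p[p$gene_id %in% iso_induced & grepl("_P1$", p$promoter_id), ]
  own_peak <- own_peak[stats::runif(nrow(own_peak)) < config$frac_induced_own_peak, ]
  ep <- rbind(p[p$is_induced_epromoter, ], own_peak)
  peak_w <- 400L
  peaks <- stats::setNames(vector("list", length(config$tf_names)),
                           config$tf_names)
  for (tf in config$tf_names) {
    hit <- stats::runif(nrow(ep)) < config$tf_peak_at_hub_prob
    center <- ep$tss + round(stats::runif(nrow(ep), -100, 100))
    df <- data.frame(chrom = ep$chrom[hit],
                     start = pmax(0L, as.integer(center[hit] - peak_w %/% 2)),
                     end = as.integer(center[hit] + peak_w %/% 2),
                     stringsAsFactors = FALSE)
    peaks[[tf]] <- df
  }
  # intergenic loci where all TFs co-bind, clear of every promoter window
  sizes <- genome$chrom_sizes
  placed <- 0
  inter <- list()
  while (placed < n_intergenic_peaks) {
    chr <- sample(names(sizes), 1)
    pos <- round(stats::runif(1, 2000, sizes[[chr]] - 2000))
    near <- p$tss[p$chrom == chr]
    if (all(abs(near - pos) > 3000)) {
      placed <- placed + 1
      inter[[placed]] <- data.frame(chrom = chr,
                                    start = as.integer(pos - peak_w %/% 2),
                                    end = as.integer(pos + peak_w %/% 2),
                                    stringsAsFactors = FALSE)
    }
  }
  inter <- do.call(rbind, inter)
  for (tf in config$tf_names)
    peaks[[tf]] <- rbind(peaks[[tf]], inter)

  # ISRE sites: >= 2 confident sites at induced Epromoters, sparse weak
  # sites elsewhere; sites within a promoter are disjoint by construction
  site_w <- 15L; gap <- 10L
  tf_pool <- c(paste0("IRF", 1:9), "STAT1", "STAT2")
  n_hub <- 2L + stats::rpois(nrow(p), max(0, config$motif_density_hub - 2))
  n_bg <- stats::rpois(nrow(p), config$motif_density_background)
  n_sites <- ifelse(p$is_induced_epromoter, n_hub, n_bg)
  rows <- list()
  # sites sit inside the strand-aware capture window (-200/+50 of the TSS)
  win_start <- ifelse(p$strand == "-", p$tss - 40L, p$tss - 190L)
  for (i in which(n_sites > 0)) {
    k <- n_sites[i]
    off <- win_start[i] - p$tss[i] + (seq_len(k) - 1L) * (site_w + gap)
    pv <- if (p$is_induced_epromoter[i]) 10^-stats::runif(k, 4.05, 8)
          else 10^-stats::runif(k, 1, 3.95)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = p$chrom[i], start = pmax(0L, p$tss[i] + off),
      end = p$tss[i] + off + site_w,
      name = sample(tf_pool, k, replace = TRUE), p_value = pv,
      stringsAsFactors = FALSE)
  }
  isre <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), p_value = numeric())
  list(peaks = peaks, isre_sites = isre)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits every file the pipeline reads: `tss.tsv`, `tads.bed`,
#' `chrom.sizes`, `counts.tsv`, `de.tsv`, one `peaks_<TF>.bed` per key TF,
#' `isre_sites.bed`, and the ground-truth tables
#' (`truth_promoters.tsv`, `truth_genes.tsv`, `truth_clusters.tsv`).
#' Byte-identical across runs for a fixed config.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @return list of generated objects, invisibly.
#' @export
simulate_fixture_set <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  counts <- simulate_starr_counts(genome, config)
  de <- simulate_de_table(genome, config)
  tracks <- simulate_tf_tracks(genome, config)
  write_table(genome$tss, file.path(dir, "tss.tsv"))
  write_bed(genome$tads, file.path(dir, "tads.bed"))
  utils::write.table(data.frame(names(genome$chrom_sizes), genome$chrom_sizes),
                     file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_table(counts, file.path(dir, "counts.tsv"))
  write_table(de, file.path(dir, "de.tsv"))
  for (tf in names(tracks$peaks))
    write_bed(tracks$peaks[[tf]], file.path(dir, paste0("peaks_", tf, ".bed")))
  write_bed(tracks$isre_sites, file.path(dir, "isre_sites.bed"))
  write_table(genome$truth$promoters, file.path(dir, "truth_promoters.tsv"))
  write_table(genome$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_table(genome$truth$clusters, file.path(dir, "truth_clusters.tsv"))
  invisible(list(genome = genome, counts = counts, de = de, tracks = tracks))
}
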