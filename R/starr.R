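#' Promoter window design
#'
#' The capture window is asymmetric around the TSS (default -200/+50 bp,
#' strand-aware); `flank` is the symmetric window used for TF-binding and
#' proximity analyses (default +/- 1 kb).
#'
#' @param upstream bp before the TSS (default 200).
#' @param downstream bp after the TSS (default 50).
#' @param flank bp either side of the TSS for binding windows (default 1000).
#' @return list of class `promoter_design`.
#' @export
promoter_design <- function(upstream = 200L, downstream = 50L, flank = 1000L) {
  stopifnot(upstream > 0, downstream > 0, flank > 0)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 flank = as.integer(flank)),
            class = "promoter_design")
}

#' STARR activity configuration
#'
#' @param fragment_extension fragment extension in nt (default 314, the
#'   average captured fragment size).
#' @param fpkm_min_input promoters with input-library FPKM below this floor
#'   are removed from all calls (default 1).
#' @param induced_ratio fold threshold on the stimulated/non-stimulated
#'   activity ratio for the induced (strictly above) and repressed (strictly
#'   below the reciprocal) calls (default 2).
#' @param pseudo_fc floor used in place of a zero non-stimulated fold-change
#'   when forming per-replicate ratios (default 0.01).
#' @param design a [promoter_design()].
#' @return list of class `starr_config`.
#' @export
starr_config <- function(fragment_extension = 314L, fpkm_min_input = 1.0,
                         induced_ratio = 2.0, pseudo_fc = 0.01,
                         design = promoter_design()) {
  stopifnot(fragment_extension > 0, fpkm_min_input > 0, induced_ratio > 0,
            pseudo_fc > 0)
  structure(list(fragment_extension = as.integer(fragment_extension),
                 fpkm_min_input = fpkm_min_input,
                 induced_ratio = induced_ratio,
                 pseudo_fc = pseudo_fc,
                 design = design),
            class = "starr_config")
}

#' Extend sequenced read intervals to fragment size
#'
#' Each fragment is anchored at the read 5' end and extended to
#' `extension_nt` in the read's direction (downstream for `+` reads,
#' upstream for `-` reads), clipped at position 0.
#'
#' @param read_intervals interval data.frame with a `strand` column of
#'   `+`/`-` values.
#' @param extension_nt fragment length in nt.
#' @return interval data.frame of fragments.
#' @export
extend_fragments <- function(read_intervals, extension_nt = 314L) {
  validate_intervals(read_intervals, "reads")
  if (is.null(read_intervals$strand) ||
      any(!read_intervals$strand %in% c("+", "-")))
    stop("extend_fragments: every read needs strand '+' or '-'")
  stopifnot(extension_nt > 0)
  plus <- read_intervals$strand == "+"
  start <- ifelse(plus, read_intervals$start,
                  pmax(0L, read_intervals$end - as.integer(extension_nt)))
  end <- ifelse(plus, read_intervals$start + as.integer(extension_nt),
                read_intervals$end)
  genomic_intervals(read_intervals$chrom, start, end, read_intervals$strand)
}

#' Count fragments covering each captured region
#'
#' A fragment counts towards a region when they share at least 1 bp.
#'
#' @param fragments interval data.frame of extended fragments.
#' @param regions interval data.frame of captured regions.
#' @return integer count per region.
#' @export
region_coverage <- function(fragments, regions) {
  count_overlaps(fragments, regions)
}

#' Fragments per kilobase of region per million mapped fragments
#'
#' @param count fragment count over the region.
#' @param region_length_bp region length in bp (> 0).
#' @param total_fragments library size (> 0).
#' @return FPKM value(s); vectorized.
#' @export
fpkm <- function(count, region_length_bp, total_fragments) {
  if (any(total_fragments <= 0)) stop("fpkm: total_fragments must be > 0")
  if (any(region_length_bp <= 0)) stop("fpkm: region length must be > 0")
  count / (region_length_bp / 1000) / (total_fragments / 1e6)
}

#' Activity fold-change with input floor
#'
#' Fold-change is reporter FPKM over input FPKM; regions whose input FPKM
#' falls below `fpkm_min_input` are flagged removed and get no fold-change.
#'
#' @param starr_fpkm,input_fpkm FPKM vectors (same length).
#' @param fpkm_min_input input floor (default 1).
#' @return data.frame with columns `fold_change` (NA when removed) and
#'   `removed`.
#' @export
activity_fold_change <- function(starr_fpkm, input_fpkm, fpkm_min_input = 1.0) {
  stopifnot(length(starr_fpkm) == length(input_fpkm),
            all(starr_fpkm >= 0), all(input_fpkm >= 0))
  removed <- input_fpkm < fpkm_min_input
  fc <- ifelse(removed, NA_real_, starr_fpkm / input_fpkm)
  data.frame(fold_change = fc, removed = removed)
}

#' Inflection point of the ranked fold-change curve
#'
#' Sorts fold-changes in decreasing order, plots `(rank, log2 fold-change)`
#' and returns the fold-change at the point of maximum perpendicular distance
#' to the chord joining the first and last points (the knee of the curve).
#' Ties are broken toward the higher rank. The result is scale-equivariant:
#' multiplying all fold-changes by a constant multiplies the threshold by the
#' same constant.
#'
#' @param fold_changes numeric vector of positive finite fold-changes
#'   (at least 3, not all equal).
#' @return the threshold tau (a fold-change value).
#' @export
inflection_threshold <- function(fold_changes) {
  fc <- fold_changes[is.finite(fold_changes)]
  if (length(fc) < 3L || any(fc <= 0))
    stop("degenerate ranked curve: need >= 3 finite positive fold-changes")
  fc <- sort(fc, decreasing = TRUE)
  y <- log2(fc)
  n <- length(y)
  if (diff(range(y)) < 1e-12)
    stop("degenerate ranked curve: all fold-changes equal")
  x <- seq_len(n)
  # distance from (x_i, y_i) to the line through (1, y1) and (n, yn)
  dx <- n - 1
  dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * 1) / sqrt(dx^2 + dy^2)
  dmax <- max(d)
  if (dmax < 1e-9 * max(1, diff(range(y))))
    stop("degenerate ranked curve: no inflection (curve is a straight line)")
  i <- max(which(d >= dmax - 1e-12 * dmax))   # ties -> higher rank
  fc[i]
}

#' Call active replicates and per-condition Epromoters
#'
#' A replicate is active when its fold-change reaches the threshold
#' (inclusive); a promoter is an Epromoter in a condition when its mean
#' fold-change over replicates reaches the threshold.
#'
#' @param rep_fc numeric matrix of per-replicate fold-changes (promoters x
#'   replicates); NA rows (removed promoters) yield NA flags.
#' @param tau activity threshold from [inflection_threshold()].
#' @return list with logical matrix `active` and logical vector `epromoter`.
#' @export
call_epromoters <- function(rep_fc, tau) {
  rep_fc <- as.matrix(rep_fc)
  list(active = rep_fc >= tau,
       epromoter = rowMeans(rep_fc) >= tau)
}

#' Call induced and repressed Epromoters from paired-condition activity
#'
#' The induction ratio is the mean over replicate pairs of
#' `FC_stim / FC_ns` (replicates paired by index; a zero non-stimulated
#' fold-change is floored at `pseudo_fc`). A promoter is an induced
#' Epromoter when the ratio is strictly greater than `induced_ratio` and at
#' least one stimulated replicate is active; repressed when the ratio is
#' strictly below `1/induced_ratio` and at least one non-stimulated
#' replicate is active.
#'
#' @param fc_stim,fc_ns fold-change matrices (promoters x replicates),
#'   columns paired by index.
#' @param active_stim,active_ns logical matrices of per-replicate activity.
#' @param induced_ratio fold threshold (default 2, strict).
#' @param pseudo_fc floor for zero non-stimulated fold-changes.
#' @return data.frame with `induction_ratio`, `induced`, `repressed`.
#' @export
call_induced_repressed <- function(fc_stim, fc_ns, active_stim, active_ns,
                                   induced_ratio = 2.0, pseudo_fc = 0.01) {
  fc_stim <- as.matrix(fc_stim); fc_ns <- as.matrix(fc_ns)
  stopifnot(identical(dim(fc_stim), dim(fc_ns)))
  denom <- pmax(fc_ns, pseudo_fc)
  ratio <- rowMeans(fc_stim / denom)
  any_stim <- rowSums(as.matrix(active_stim), na.rm = TRUE) >= 1
  any_ns <- rowSums(as.matrix(active_ns), na.rm = TRUE) >= 1
  data.frame(induction_ratio = ratio,
             induced = ratio > induced_ratio & any_stim,
             repressed = ratio < 1 / induced_ratio & any_ns)
}

#' Quantify promoter enhancer activity and call Epromoters
#'
#' Full activity stage: FPKM-normalize input and reporter counts per
#' condition and replicate, form fold-changes, remove promoters failing the
#' input FPKM floor, derive the per-condition activity threshold from the
#' inflection point of the ranked mean fold-change of retained promoters,
#' and call per-condition Epromoters plus induced/repressed/constitutive
#' status across the two conditions.
#'
#' @param count_table long count table (see [read_count_table()]) with two
#'   conditions.
#' @param regions interval data.frame of captured promoter windows with a
#'   `name` column holding promoter ids (one row per promoter).
#' @param config a [starr_config()].
#' @param condition_ns,condition_stim the two condition labels in
#'   `count_table` (defaults `"ns"`, `"stim"`).
#' @return data.frame with one row per promoter: per-condition replicate
#'   fold-changes (`fc_<cond>_r<i>`), mean fold-changes, activity and
#'   Epromoter flags, `induction_ratio`, `induced_epromoter`,
#'   `repressed_epromoter`, `constitutive_epromoter` and `removed`. The
#'   per-condition thresholds are attached as attribute `tau`.
#' @export
quantify_activity <- function(count_table, regions, config = starr_config(),
                              condition_ns = "ns", condition_stim = "stim") {
  stopifnot(inherits(config, "starr_config"))
  if (is.null(regions$name)) stop("regions need a 'name' column (promoter id)")
  conds <- c(condition_ns, condition_stim)
  if (!all(conds %in% count_table$condition))
    stop("count table lacks condition(s): ",
         paste(setdiff(conds, count_table$condition), collapse = ", "))
  ct <- count_table[count_table$condition %in% conds, ]
  prom <- regions$name
  len <- regions$end - regions$start
  reps <- sort(unique(ct$replicate))
  arr <- function(lib) {
    sub <- ct[ct$library == lib, ]
    a <- array(0, dim = c(length(prom), length(conds), length(reps)),
               dimnames = list(prom, conds, as.character(reps)))
    idx <- cbind(match(sub$region_id, prom),
                 match(sub$condition, conds),
                 match(sub$replicate, reps))
    if (anyNA(idx[, 1]))
      stop("count table region_id absent from regions: ",
           sub$region_id[which(is.na(idx[, 1]))[1]])
    a[idx] <- sub$count
    a
  }
  cin <- arr("input"); cst <- arr("starr")
  totals_in <- apply(cin, c(2, 3), sum)
  totals_st <- apply(cst, c(2, 3), sum)
  fpkm_in <- cin; fpkm_st <- cst
  for (j in seq_along(conds)) for (k in seq_along(reps)) {
    fpkm_in[, j, k] <- fpkm(cin[, j, k], len, totals_in[j, k])
    fpkm_st[, j, k] <- fpkm(cst[, j, k], len, totals_st[j, k])
  }
  removed <- apply(fpkm_in < config$fpkm_min_input, 1, any)
  fc <- fpkm_st / fpkm_in
  fc[removed, , ] <- NA_real_

  fc_ns <- matrix(fc[, 1, ], nrow = length(prom))
  fc_st <- matrix(fc[, 2, ], nrow = length(prom))
  mean_ns <- rowMeans(fc_ns)
  mean_st <- rowMeans(fc_st)
  tau <- c(inflection_threshold(mean_ns[!removed]),
           inflection_threshold(mean_st[!removed]))
  names(tau) <- conds
  call_ns <- call_epromoters(fc_ns, tau[1])
  call_st <- call_epromoters(fc_st, tau[2])
  ir <- call_induced_repressed(fc_st, fc_ns, call_st$active, call_ns$active,
                               config$induced_ratio, config$pseudo_fc)
  out <- data.frame(promoter_id = prom, removed = removed,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reps)) {
    out[[paste0("fc_", condition_ns, "_r", reps[k])]] <- fc_ns[, k]
    out[[paste0("fc_", condition_stim, "_r", reps[k])]] <- fc_st[, k]
  }
  out[[paste0("mean_fc_", condition_ns)]] <- mean_ns
  out[[paste0("mean_fc_", condition_stim)]] <- mean_st
  out[[paste0("epromoter_", condition_ns)]] <- call_ns$epromoter & !removed
  out[[paste0("epromoter_", condition_stim)]] <- call_st$epromoter & !removed
  out$induction_ratio <- ifelse(removed, NA_real_, ir$induction_ratio)
  # induced/repressed calls apply to promoters that ARE Epromoters in the
  # gained condition (activity above the inflection threshold)
  out$induced_epromoter <- ir$induced & !removed &
    out[[paste0("epromoter_", condition_stim)]]
  out$repressed_epromoter <- ir$repressed & !removed &
    out[[paste0("epromoter_", condition_ns)]]
  out$constitutive_epromoter <- out[[paste0("epromoter_", condition_ns)]] &
    out[[paste0("epromoter_", condition_stim)]] &
    !out$induced_epromoter & !out$repressed_epromoter
  attr(out, "tau") <- tau
  out
}
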