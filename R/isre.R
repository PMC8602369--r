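#' ISRE motif-site configuration
#'
#' @param isre_tfs TF labels whose motif sites constitute the pan-ISRE track
#'   (default IRF1-IRF9 plus STAT1/STAT2).
#' @param high_conf_p ceiling on the motif-match p-value for the
#'   high-confidence tier (default 1e-4, strict).
#' @param design a [promoter_design()]; the capture window is the default
#'   counting window.
#' @return list of class `motif_config`.
#' @export
motif_config <- function(isre_tfs = c(paste0("IRF", 1:9), "STAT1", "STAT2"),
                         high_conf_p = 1e-4, design = promoter_design()) {
  stopifnot(high_conf_p > 0, high_conf_p < 1)
  structure(list(isre_tfs = isre_tfs, high_conf_p = high_conf_p,
                 design = design),
            class = "motif_config")
}

#' Merge per-TF motif sites into a non-redundant pan-ISRE track
#'
#' Sites of all configured TFs are pooled and merged at >= 1 bp overlap so
#' that stacked motifs of different factors count as a single ISRE site.
#' Sets labeled with a TF outside the configured list are skipped with a
#' warning.
#'
#' @param site_sets named list of interval data.frames, one per TF; sites
#'   may carry a `p_value` column.
#' @param config a [motif_config()].
#' @return disjoint sorted interval data.frame.
#' @export
pan_isre_track <- function(site_sets, config = motif_config()) {
  stopifnot(!is.null(names(site_sets)))
  unknown <- setdiff(names(site_sets), config$isre_tfs)
  if (length(unknown)) {
    warning("skipping unknown TF set(s): ", paste(unknown, collapse = ", "))
    site_sets <- site_sets[names(site_sets) %in% config$isre_tfs]
  }
  if (length(site_sets) == 0L)
    return(genomic_intervals(character(), integer(), integer())[0, c("chrom", "start", "end")])
  pooled <- do.call(rbind, lapply(site_sets, function(s)
    s[, c("chrom", "start", "end")]))
  merge_intervals(pooled)
}

#' Keep only high-confidence motif sites
#'
#' Retains sites with `p_value < p_max` (strict). Sites lacking a p-value
#' are excluded from the high-confidence tier, with a message.
#'
#' @param site_sets named list of interval data.frames with `p_value`.
#' @param p_max p-value ceiling (default 1e-4).
#' @return list of filtered site sets.
#' @export
highconf_filter <- function(site_sets, p_max = 1e-4) {
  lapply(site_sets, function(s) {
    if (is.null(s$p_value)) {
      message("site set without p-values: all sites excluded from the ",
              "high-confidence tier")
      return(s[0, , drop = FALSE])
    }
    no_p <- is.na(s$p_value)
    if (any(no_p))
      message(sum(no_p), " site(s) without p-value excluded from the ",
              "high-confidence tier")
    s[!no_p & s$p_value < p_max, , drop = FALSE]
  })
}

#' Count non-redundant ISRE sites per promoter window
#'
#' Counts merged sites overlapping each window by >= 1 bp and classifies
#' promoters into the 0 / 1 / >=2 site classes. The "all sites" tier merges
#' before counting; the high-confidence tier filters sites on p-value first
#' and merges afterwards, so weak sites cannot bridge two confident sites
#' into one.
#'
#' @param promoter_windows interval data.frame with `name` column (typically
#'   the capture window from [capture_windows()]).
#' @param site_sets named list of per-TF site data.frames with `p_value`.
#' @param config a [motif_config()].
#' @return data.frame with `promoter_id`, `n_sites_all`, `n_sites_highconf`,
#'   `class_all`, `class_highconf` (`"0"`, `"1"`, `">=2"`).
#' @export
count_isre <- function(promoter_windows, site_sets, config = motif_config()) {
  track_all <- pan_isre_track(site_sets, config)
  track_hc <- pan_isre_track(suppressMessages(
    highconf_filter(site_sets, config$high_conf_p)), config)
  n_all <- if (nrow(track_all)) count_overlaps(track_all, promoter_windows)
           else integer(nrow(promoter_windows))
  n_hc <- if (nrow(track_hc)) count_overlaps(track_hc, promoter_windows)
          else integer(nrow(promoter_windows))
  cls <- function(n) ifelse(n >= 2L, ">=2", as.character(n))
  data.frame(promoter_id = promoter_windows$name,
             n_sites_all = n_all, n_sites_highconf = n_hc,
             class_all = cls(n_all), class_highconf = cls(n_hc),
             stringsAsFactors = FALSE)
}
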