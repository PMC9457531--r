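#' Per-day genus relative abundance
#'
#' Divides each genus count by the day's total read count, exactly the
#' amplicon convention of comparing sequences assigned to a genus with the
#' total sequences of the sample. Fractions therefore sum to 1 per day over
#' the table's genera (an `Other` row, when present, carries the remainder).
#'
#' @param table A [genus_counts()] table.
#' @param degradation_label Optional `"degraded"`/`"stable"` label attached
#'   to the series (usually from [classify_degradation()]).
#' @return An `abundance_series`: `sample_id`, `days`, genus x day
#'   `abundance` matrix, per-day `totals`, `degradation_label`.
#' @export
relative_abundance <- function(table, degradation_label = NA_character_) {
  stopifnot(inherits(table, "genus_counts"))
  totals <- colSums(table$counts)
  if (any(totals == 0))
    stop("zero total reads at day ", table$days[which(totals == 0)[1L]])
  structure(list(sample_id = table$sample_id, days = table$days,
                 abundance = sweep(table$counts, 2L, totals, `/`),
                 totals = totals,
                 degradation_label = degradation_label),
            class = "abundance_series")
}

#' Classify a degradation curve
#'
#' A curve is `degraded` when the final concentration is at most
#' `residual_frac` of the initial one (default 10% residual); otherwise
#' `stable`. For degraded curves the onset day is the first day at which
#' the concentration drops below 90% of the initial value -- the end of the
#' lag (adaptation) phase.
#'
#' @param curve A [degradation_curve()].
#' @param residual_frac Residual fraction defining degradation (default
#'   0.10).
#' @return List with `label` (`"degraded"`/`"stable"`) and `onset_day`
#'   (`NA` for stable curves).
#' @export
#' @examples
#' cv <- degradation_curve(0:8, c(100, 100, 100, 100, 100, 95, 40, 2, 1))
#' classify_degradation(cv)  # degraded, onset day 6
classify_degradation <- function(curve, residual_frac = 0.10) {
  stopifnot(inherits(curve, "degradation_curve"))
  conc <- curve$concentration
  if (length(conc) < 2L) stop("need at least two timepoints")
  if (conc[1L] <= 0) stop("initial concentration must be positive")
  degraded <- conc[length(conc)] <= residual_frac * conc[1L]
  onset <- NA_integer_
  if (degraded) {
    below <- which(conc < 0.9 * conc[1L])
    onset <- curve$days[below[1L]]
  }
  list(label = if (degraded) "degraded" else "stable", onset_day = onset)
}

group_enriched <- function(series, genus, min_peak, min_fold) {
  # enriched within a group iff the rule holds in EVERY sample of the group
  all(vapply(series, function(s) {
    ab <- if (genus %in% rownames(s$abundance))
      s$abundance[genus, ] else rep(0, length(s$days))
    peak <- max(ab)
    baseline <- ab[1L]
    floorv <- max(baseline, 1 / s$totals[1L])
    peak >= min_peak && peak >= min_fold * floorv
  }, TRUE))
}

#' Call degradation-associated enriched genera
#'
#' A genus is enriched within a sample group (degraded vs stable) when in
#' every sample of the group its peak abundance reaches `min_peak` and
#' exceeds `min_fold` times the baseline (day-0) abundance, floored at a
#' pseudo-abundance of one read to keep zero baselines finite. A genus is
#' degradation-associated when it is enriched in the degraded group and not
#' in the stable group.
#'
#' @param series List of `abundance_series`, each with a non-`NA`
#'   `degradation_label`; both groups must be represented.
#' @param min_peak Minimum peak relative abundance (default 0.05).
#' @param min_fold Minimum peak/baseline fold change (default 5).
#' @return data.frame with one row per genus: `genus`, `peak_day`,
#'   `peak_abundance`, `baseline_abundance` (means over degraded samples),
#'   `enriched_in_degraders`, `enriched_in_nondegraders`,
#'   `degradation_associated`.
#' @export
call_enriched_genera <- function(series, min_peak = 0.05, min_fold = 5) {
  labels <- vapply(series, `[[`, "", "degradation_label")
  if (anyNA(labels) || !all(labels %in% c("degraded", "stable")))
    stop("every series needs a degradation_label of 'degraded' or 'stable'")
  deg <- series[labels == "degraded"]
  sta <- series[labels == "stable"]
  if (length(deg) == 0L || length(sta) == 0L)
    stop("need at least one degraded and one stable sample")
  days <- deg[[1L]]$days
  genera <- sort(unique(unlist(lapply(series, function(s)
    rownames(s$abundance)))))
  rows <- lapply(genera, function(g) {
    traj <- rowMeans(vapply(deg, function(s) {
      if (g %in% rownames(s$abundance)) s$abundance[g, ]
      else rep(0, length(s$days))
    }, numeric(length(days))))
    pk <- which.max(traj)
    e_deg <- group_enriched(deg, g, min_peak, min_fold)
    e_sta <- group_enriched(sta, g, min_peak, min_fold)
    data.frame(genus = g, peak_day = days[pk], peak_abundance = traj[pk],
               baseline_abundance = traj[1L],
               enriched_in_degraders = e_deg,
               enriched_in_nondegraders = e_sta,
               degradation_associated = e_deg && !e_sta)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
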