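# Expression-array quality metrics used to predict matching performance:
# an array with no usable signal cannot support genotype prediction, and its
# minimum score is uninformative rather than evidence of a mix-up.

#' Signal-level percentiles of an expression array
#'
#' The 95th percentile of log-intensities (P95) is a crude signal-level
#' statistic; the 5th percentile (P05) is the corresponding background
#' baseline.  P95 has no absolute interpretation across batches or scanner
#' settings, but a P95 close to P05 marks an array with no signal.
#' Percentiles use linear interpolation (scanner software conventions
#' differ; this pins the definition).
#'
#' @param x numeric vector of an array's log-intensities.
#' @return list with `p95` and `p05` (log-intensity units).
#' @export
p95_metric <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 20)
    stop("need at least 20 non-missing probe values")
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  list(p95 = q[2], p05 = q[1])
}

#' Rank separation between well-designed and intergenic probes
#'
#' Probes are ranked by intensity (ascending, mean rank for ties); the
#' statistic is the mean rank of perfect-tier probes minus the mean rank of
#' intergenic probes, divided by the total probe count so values are
#' comparable across platforms.  A healthy array shows strongly positive
#' separation; pure noise gives about zero; an array with no sample can go
#' substantially negative when background structure favours the intergenic
#' probes.  Being rank-based, the score is invariant under any strictly
#' monotone transform of the intensities.
#'
#' @param x numeric vector of an array's log-intensities (probe order
#'   matching `probe_annotation`).
#' @param probe_annotation data.frame with a `quality_tier` column.
#' @return dimensionless score in `(-1, 1)`.
#' @export
signal_separation_metric <- function(x, probe_annotation) {
  tier <- probe_annotation$quality_tier
  perfect <- which(tier == "perfect")
  inter <- which(tier == "intergenic")
  if (length(perfect) < 10 || length(inter) < 10)
    stop("need at least 10 perfect-tier and 10 intergenic probes")
  r <- rank(x, ties.method = "average", na.last = "keep")
  (mean(r[perfect], na.rm = TRUE) - mean(r[inter], na.rm = TRUE)) / length(x)
}

#' Association between array quality and minimum score
#'
#' A quality metric that predicts the minimum score tells reviewers whether
#' an apparent mismatch is evidence of a plating error or merely of a failed
#' hybridisation.  Reports the Spearman rank correlation, a quartile-binned
#' summary, and flags arrays scheduled to be empty that nevertheless show
#' signal (and arrays with samples that look empty).
#'
#' @param quality named numeric vector of quality scores per expression
#'   array (e.g. [signal_separation_metric()] values).
#' @param deltas data.frame from [delta_statistic()].
#' @param scheduled_empty character vector of array ids expected to carry no
#'   sample.
#' @return list with `spearman`, `bins` (quartile summary), `flags`.
#' @export
quality_vs_minscore <- function(quality, deltas, scheduled_empty = character()) {
  common <- intersect(names(quality), deltas$expression_array)
  if (length(common) < 3)
    stop("need at least 3 arrays present in both inputs")
  q <- quality[common]
  ms <- deltas$min_score[match(common, deltas$expression_array)]
  rho <- if (stats::sd(q) == 0 || stats::sd(ms) == 0) NA_real_
         else suppressWarnings(stats::cor(q, ms, method = "spearman"))

  br <- unique(stats::quantile(q, seq(0, 1, 0.25)))
  bins <- if (length(br) > 2) {
    grp <- cut(q, br, include.lowest = TRUE)
    data.frame(bin = levels(grp),
               n = as.vector(table(grp)),
               mean_min_score = as.vector(tapply(ms, grp, mean)),
               stringsAsFactors = FALSE)
  } else data.frame(bin = "all", n = length(q), mean_min_score = mean(ms),
                    stringsAsFactors = FALSE)

  flags <- character()
  empty_here <- intersect(scheduled_empty, common)
  occupied <- setdiff(common, scheduled_empty)
  if (length(empty_here) && length(occupied)) {
    thr_hi <- stats::quantile(q[occupied], 0.25)
    lively <- empty_here[q[empty_here] >= thr_hi]
    if (length(lively))
      flags <- c(flags, paste0("scheduled-empty array shows signal: ", lively))
    thr_lo <- max(q[empty_here])
    dead <- occupied[q[occupied] <= thr_lo]
    if (length(dead))
      flags <- c(flags, paste0("array with sample looks empty: ", dead))
  }
  list(spearman = rho, bins = bins, flags = flags)
}
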