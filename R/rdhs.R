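#' Filter pooled DNase peaks
#'
#' Applies the three peak-level filters used before rDHS construction:
#' signal above the global percentile floor (computed over the signals of
#' ALL pooled peaks, not per experiment), width within `[width_min,
#' width_max]` bp, and FDR strictly below `fdr_max`. Peaks with `NA` FDR
#' (no FDR recorded in the source file) pass the FDR filter, with a warning.
#'
#' The percentile floor is nearest-rank over the pooled sorted signals:
#' the floor is `sort(signal)[ceiling(pct/100 * n)]` and peaks must exceed
#' it strictly.
#'
#' @param peaks `GRanges` of pooled DNase peaks from all experiments, with
#'   metadata columns `signal` and `fdr` (see [read_peaks()]).
#' @param signal_floor_pct Percentile cutoff (default 10).
#' @param width_min,width_max Retained widths in bp (defaults 150, 350).
#' @param fdr_max FDR cutoff (default 1e-3, strict `<`).
#' @return The retained peaks in input order.
#' @export
filter_dnase_peaks <- function(peaks, signal_floor_pct = 10,
                               width_min = 150L, width_max = 350L,
                               fdr_max = 1e-3) {
  if (!length(peaks)) {
    warning("empty pooled peak set")
    return(peaks)
  }
  signal <- peaks$signal
  if (any(!is.finite(signal))) stop("non-finite peak signal")
  floor_val <- signal_floor(signal, signal_floor_pct)
  w <- GenomicRanges::width(peaks)
  fdr <- peaks$fdr
  if (anyNA(fdr)) warning(sum(is.na(fdr)), " peak(s) without FDR pass the FDR filter")
  keep <- signal > floor_val &
    w >= width_min & w <= width_max &
    (is.na(fdr) | fdr < fdr_max)
  peaks[keep]
}

#' Nearest-rank percentile floor
#'
#' @param x Numeric vector of pooled peak signals.
#' @param pct Percentile in `[0, 100]`. `pct = 0` imposes no floor
#'   (returns `-Inf`), so every peak passes the strict comparison.
#' @return The value at nearest rank `ceiling(pct/100 * length(x))` of the
#'   sorted vector.
#' @export
signal_floor <- function(x, pct) {
  n <- length(x)
  if (!n) stop("cannot take a percentile of an empty vector")
  r <- ceiling(pct / 100 * n)
  if (r < 1) return(-Inf)
  sort(x)[r]
}

#' Build representative DHSs from filtered peaks
#'
#' Greedy reduction of the pooled, overlapping peak set to non-overlapping
#' representative DHSs: among peaks not yet represented, the highest-signal
#' peak becomes the next rDHS; every peak overlapping it by at least one
#' base pair is marked represented; repeat until all peaks are represented.
#' rDHSs inherit the exact coordinates of their winning peak.
#'
#' Ties on signal are broken by lowest (chrom, start, end, experiment_id),
#' which makes the result invariant to input order.
#'
#' @param peaks Filtered `GRanges` of DNase peaks (`signal`, `experiment_id`
#'   metadata columns; signals finite).
#' @return `GRanges` of rDHSs sorted by coordinate, with metadata columns
#'   `rdhs_id`, `signal`, `experiment_id`, `represented_peaks` (the number
#'   of input peaks overlapping the rDHS by >= 1 bp; a peak overlapping two
#'   rDHSs is counted by both) and `source_peak` (index into `peaks`).
#' @export
build_rdhss <- function(peaks) {
  n <- length(peaks)
  if (!n) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      rdhs_id = character(0), signal = numeric(0),
      experiment_id = character(0), represented_peaks = integer(0),
      source_peak = integer(0))
    return(out)
  }
  if (any(!is.finite(peaks$signal))) stop("non-finite peak signal")
  eid <- peaks$experiment_id
  if (is.null(eid)) eid <- rep(NA_character_, n)
  priority <- order(-peaks$signal,
                    as.character(GenomicRanges::seqnames(peaks)),
                    GenomicRanges::start(peaks),
                    GenomicRanges::end(peaks),
                    eid)
  hits <- GenomicRanges::findOverlaps(peaks, peaks)
  adj <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  represented <- logical(n)
  winners <- integer(0)
  for (i in priority) {
    if (represented[i]) next
    winners <- c(winners, i)
    represented[adj[[as.character(i)]]] <- TRUE
  }
  out <- peaks[winners]
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$signal <- peaks$signal[winners]
  S4Vectors::mcols(out)$experiment_id <- eid[winners]
  S4Vectors::mcols(out)$represented_peaks <-
    GenomicRanges::countOverlaps(out, peaks)
  S4Vectors::mcols(out)$source_peak <- winners
  o <- order(as.character(GenomicRanges::seqnames(out)),
             GenomicRanges::start(out), GenomicRanges::end(out))
  out <- out[o]
  S4Vectors::mcols(out)$rdhs_id <- sprintf("RDHS%06d", seq_along(out))
  S4Vectors::mcols(out) <- S4Vectors::mcols(out)[c("rdhs_id", "signal",
                                                   "experiment_id",
                                                   "represented_peaks",
                                                   "source_peak")]
  out
}

#' Filter rDHSs against a consensus-DHS set
#'
#' Retains only rDHSs overlapping some consensus DHS by at least one base
#' pair, the false-positive reduction step applied when an independently
#' derived consensus set is available.
#'
#' @param rdhss `GRanges` of rDHSs.
#' @param cdhs `GRanges` of consensus DHSs, or `NULL` to disable the stage
#'   (identity).
#' @return The retained rDHSs.
#' @export
filter_by_consensus <- function(rdhss, cdhs) {
  if (is.null(cdhs)) return(rdhss)
  if (!length(cdhs)) {
    warning("empty consensus-DHS set: all rDHSs discarded")
    return(rdhss[0])
  }
  IRanges::subsetByOverlaps(rdhss, cdhs, minoverlap = 1L)
}
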