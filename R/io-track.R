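#' Read a bedGraph signal track
#'
#' Loads a bedGraph file into a piecewise-constant per-base coverage
#' structure. Records on the same chromosome must not overlap (adjacent is
#' fine); positions not covered by any record read as 0.
#'
#' @param path Path to the bedGraph file.
#' @param assay Assay name, one of [core_assays()].
#' @param biosample_id Biosample the track was measured in.
#' @return A `SignalTrack` object (list with the per-chromosome `RleList`
#'   coverage in `$cov` plus `$assay` and `$biosample_id`).
#' @export
read_signal_track <- function(path, assay = NA_character_,
                              biosample_id = NA_character_) {
  if (!file.exists(path)) stop("signal track does not exist: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr)) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(hits))
      stop("overlapping bedGraph records in ", path, ": intervals ",
           S4Vectors::queryHits(hits)[1], " and ", S4Vectors::subjectHits(hits)[1],
           " overlap")
    if (any(gr$score < 0))
      stop("negative signal values in ", path)
  }
  cov <- GenomicRanges::coverage(gr, weight = "score")
  structure(list(cov = cov, assay = assay, biosample_id = biosample_id),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: assay=%s biosample=%s chromosomes=%d\n",
              x$assay, x$biosample_id, length(x$cov)))
  invisible(x)
}

#' Average signal over (possibly flanked) intervals
#'
#' Computes, for each query interval, the arithmetic mean of the per-base
#' track values over the window obtained by extending the interval by
#' `flank_bp` on each side. Windows are clipped at position 0; positions
#' beyond the track's covered span contribute 0 to the numerator but still
#' count in the denominator, which is the clipped window width. This mirrors
#' averaging a genome-wide signal file over a BED interval.
#'
#' DNase and CTCF signals are averaged over the rDHS itself
#' (`flank_bp = 0`); H3K4me3 and H3K27ac over the rDHS plus a 500-bp flank on
#' each side, to capture the histone marks on flanking nucleosomes.
#'
#' @param track A `SignalTrack`.
#' @param regions `GRanges` of intervals (e.g. rDHSs).
#' @param flank_bp Flank in bp added to each side of every interval.
#' @return Numeric vector of mean signals, one per interval.
#' @export
average_signal <- function(track, regions, flank_bp = 0L) {
  stopifnot(inherits(track, "SignalTrack"), flank_bp >= 0)
  n <- length(regions)
  out <- numeric(n)
  if (!n) return(out)
  s <- pmax(GenomicRanges::start(regions) - as.integer(flank_bp), 1L)
  e <- GenomicRanges::end(regions) + as.integer(flank_bp)
  w <- e - s + 1L
  chroms <- as.character(GenomicRanges::seqnames(regions))
  missing_chroms <- character(0)
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    r <- track$cov[[ch]]
    if (is.null(r) || length(r) == 0L) {
      missing_chroms <- c(missing_chroms, ch)
      out[idx] <- 0
      next
    }
    len <- length(r)
    cs <- s[idx]
    ce <- pmin(e[idx], len)
    sums <- numeric(length(idx))
    ok <- cs <= ce
    if (any(ok))
      sums[ok] <- IRanges::viewSums(IRanges::Views(r, start = cs[ok], end = ce[ok]))
    out[idx] <- sums / w[idx]
  }
  if (length(missing_chroms))
    warning("chromosome(s) absent from track, mean taken as 0: ",
            paste(missing_chroms, collapse = ", "))
  out
}
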