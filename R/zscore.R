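#' Within-biosample Z-scores of log10 signal
#'
#' Transforms a vector of mean raw signals (one entry per rDHS, for a single
#' biosample and assay) to Z-scores of log10 signal. The mean and standard
#' deviation are computed over the log10 of the NONZERO entries only
#' (population convention, divide by N); entries with raw signal 0 receive
#' the sentinel Z of -10, marking "no signal" unambiguously below any real
#' score. Degenerate vectors (fewer than two nonzero entries, or all nonzero
#' entries identical) get Z = 0 at their nonzero entries, with a warning.
#'
#' This within-biosample standardization is what makes DNase-seq read-count
#' signal and ChIP-seq fold-change signal comparable across biosamples.
#'
#' @param values Numeric vector of mean signals, all `>= 0`.
#' @param zero_sentinel Z assigned to zero raw signal (default -10).
#' @return Numeric vector of Z-scores, same length and order as `values`.
#' @export
zscore_biosample <- function(values, zero_sentinel = -10) {
  stopifnot(is.numeric(values))
  if (any(values < 0, na.rm = TRUE)) stop("raw signals must be >= 0")
  z <- rep(zero_sentinel, length(values))
  z[is.na(values)] <- NA_real_
  nz <- which(!is.na(values) & values > 0)
  if (length(nz) < 2) {
    if (length(nz)) {
      warning("fewer than 2 nonzero signals; Z set to 0 for nonzero entries")
      z[nz] <- 0
    }
    return(z)
  }
  lx <- log10(values[nz])
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma == 0) {
    warning("all nonzero signals identical; Z set to 0 for nonzero entries")
    z[nz] <- 0
  } else {
    z[nz] <- (lx - mu) / sigma
  }
  z
}

#' Compute the rDHS x biosample x assay Z-score matrix
#'
#' Averages each biosample's signal tracks over the rDHSs (DNase and CTCF
#' over the rDHS itself, H3K4me3 and H3K27ac over the rDHS extended by
#' `flank_histone` bp on each side), applies [zscore_biosample()] per
#' (biosample, assay), and reduces to the per-assay maximum Z across
#' biosamples (max-Z). Assays a biosample lacks are missing (`NA`), never
#' zero-filled, and are ignored by the max.
#'
#' @param rdhss `GRanges` of rDHSs with an `rdhs_id` column.
#' @param tracks Nested list: `tracks[[biosample_id]][[assay]]` is a
#'   `SignalTrack` (absent assays omitted or `NULL`).
#' @param flank_histone Flank for H3K4me3/H3K27ac averaging (default 500).
#' @param zero_sentinel Passed to [zscore_biosample()].
#' @return A `ZScoreMatrix`: list with 3-d arrays `raw` and `z`
#'   (rDHS x biosample x assay), matrix `maxz` (rDHS x assay, `NA` when no
#'   biosample has the assay), logical `availability`
#'   (biosample x assay), and `rdhs_id`.
#' @export
compute_zscore_matrix <- function(rdhss, tracks, flank_histone = 500L,
                                  zero_sentinel = -10) {
  assays <- core_assays()
  biosamples <- names(tracks)
  if (is.null(biosamples) || !length(biosamples))
    stop("no biosample tracks supplied")
  n <- length(rdhss)
  dims <- list(rdhs = rdhss$rdhs_id, biosample = biosamples, assay = assays)
  raw <- array(NA_real_, dim = c(n, length(biosamples), 4), dimnames = dims)
  z <- raw
  availability <- matrix(FALSE, length(biosamples), 4,
                         dimnames = list(biosamples, assays))
  for (b in biosamples) {
    for (a in assays) {
      tr <- tracks[[b]][[a]]
      if (is.null(tr)) next
      availability[b, a] <- TRUE
      raw[, b, a] <- average_signal(tr, rdhss,
                                    flank_bp = assay_flank(a, flank_histone))
      z[, b, a] <- zscore_biosample(raw[, b, a], zero_sentinel = zero_sentinel)
    }
  }
  maxz <- matrix(NA_real_, n, 4, dimnames = dims[c(1, 3)])
  for (a in assays) {
    have <- availability[, a]
    if (any(have))
      maxz[, a] <- apply(z[, have, a, drop = FALSE], 1, max)
  }
  structure(list(raw = raw, z = z, maxz = maxz,
                 availability = availability, rdhs_id = rdhss$rdhs_id),
            class = "ZScoreMatrix")
}

#' Per-assay maximum Z-score across biosamples
#'
#' @param zm A `ZScoreMatrix`.
#' @param assay Assay name; omit for the full rDHS x assay max-Z matrix.
#' @return Numeric vector (or matrix) of max-Z values; `NA` where no
#'   biosample has the assay, which downstream classification treats as
#'   unascertained.
#' @export
max_z <- function(zm, assay = NULL) {
  stopifnot(inherits(zm, "ZScoreMatrix"))
  if (is.null(assay)) return(zm$maxz)
  stopifnot(assay %in% colnames(zm$maxz))
  zm$maxz[, assay]
}

#' @export
print.ZScoreMatrix <- function(x, ...) {
  cat(sprintf("ZScoreMatrix: %d rDHS x %d biosample(s) x 4 assays (%d assay slots available)\n",
              dim(x$z)[1], dim(x$z)[2], sum(x$availability)))
  invisible(x)
}
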