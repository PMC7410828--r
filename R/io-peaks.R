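#' Read DNase peak calls
#'
#' Reads an ENCODE narrowPeak or plain BED6+ file of DNase peaks into a
#' `GRanges`. Input coordinates are BED-style 0-based half-open and are
#' converted to the 1-based closed convention `GRanges` uses; widths are
#' preserved exactly.
#'
#' For narrowPeak, the signal is column 7 (`signalValue`) and the FDR is
#' recovered from column 9 (`qValue`), which the narrowPeak standard stores as
#' -log10(FDR); a `qValue` of -1 (not available) yields `NA`. For `bed6+` the
#' signal and optional FDR column indices must be given and the FDR column is
#' taken as a plain rate in `[0, 1]`.
#'
#' @param path Path to the peak file.
#' @param format `"narrowPeak"` (10 columns) or `"bed6+"`.
#' @param experiment_id Identifier of the DNase experiment the peaks came
#'   from; stored on every peak.
#' @param signal_col,fdr_col 1-based column indices of the signal and FDR
#'   columns for `format = "bed6+"`; `fdr_col = NULL` leaves FDR `NA`.
#' @return `GRanges` with metadata columns `name`, `signal`, `fdr`,
#'   `experiment_id`, in input order.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6+"),
                       experiment_id = NA_character_,
                       signal_col = 7L, fdr_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.empty_peaks())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (format == "narrowPeak") 10L
              else max(6L, signal_col, if (is.null(fdr_col)) 0L else fdr_col)
  bad <- which(nf < min_cols)
  if (length(bad))
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields, found %d",
                 format, bad[1], path, min_cols, nf[bad[1]]))

  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x)) {
      ln <- which(is.na(x))[1]
      stop(sprintf("parse error at line %d of %s: non-numeric %s field '%s'",
                   ln, path, what, col(i)[ln]))
    }
    x
  }

  chrom <- col(1)
  start0 <- num(2, "start")
  end0 <- num(3, "end")
  if (any(start0 < 0) || any(end0 <= start0)) {
    ln <- which(start0 < 0 | end0 <= start0)[1]
    stop(sprintf("invalid interval at line %d of %s: [%g, %g)",
                 ln, path, start0[ln], end0[ln]))
  }
  name <- if (all(nf >= 4)) col(4) else NA_character_

  if (format == "narrowPeak") {
    signal <- num(7, "signalValue")
    qval <- num(9, "qValue")
    fdr <- ifelse(qval < 0, NA_real_, 10^(-qval))
  } else {
    signal <- num(signal_col, "signal")
    fdr <- if (is.null(fdr_col)) NA_real_ else num(fdr_col, "FDR")
  }
  if (any(!is.finite(signal)) || any(signal < 0)) {
    ln <- which(!is.finite(signal) | signal < 0)[1]
    stop(sprintf("invalid signal at line %d of %s: signal must be finite and >= 0", ln, path))
  }
  okf <- is.na(fdr) | (fdr >= 0 & fdr <= 1)
  if (!all(okf))
    stop(sprintf("invalid FDR at line %d of %s: must lie in [0, 1]",
                 which(!okf)[1], path))

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0))
  )
  S4Vectors::mcols(gr)$name <- name
  S4Vectors::mcols(gr)$signal <- signal
  S4Vectors::mcols(gr)$fdr <- fdr
  S4Vectors::mcols(gr)$experiment_id <- experiment_id
  gr
}

.empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), signal = numeric(0), fdr = numeric(0),
    experiment_id = character(0))
  gr
}
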