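#' Extract transcription start sites
#'
#' Builds the set of unique TSS points used for distance-based
#' classification: the 5' end of every annotated transcript carrying the
#' configured tag ("basic" by default, matching GENCODE basic transcripts).
#' For a + strand transcript the TSS is its start; for a - strand transcript
#' its end. Distinct transcripts sharing a 5' end collapse to one point.
#'
#' Accepts either a GTF file with transcript records or a precomputed BED
#' file of point intervals (the start of each BED record is taken as the TSS
#' position; strand is read from column 6 when present).
#'
#' @param path GTF (`.gtf`) or BED file.
#' @param tag_filter GTF `tag` attribute value a transcript must carry to be
#'   retained; `NULL` or `NA` retains all transcripts. Ignored for BED input.
#'   If the annotation has no `tag` attribute at all, every transcript is
#'   kept and a message is emitted.
#' @param feature_type GTF feature type holding transcripts (default
#'   `"transcript"`).
#' @return `GRanges` of width-1 TSS points (unique by chromosome and
#'   position; strand retained for reporting). The number of strand-less
#'   transcripts skipped is attached as attribute `n_skipped_no_strand`.
#' @export
extract_tss <- function(path, tag_filter = "basic", feature_type = "transcript") {
  if (!file.exists(path)) stop("TSS annotation does not exist: ", path)
  if (grepl("\\.(gtf|gff[23]?)(\\.gz)?$", path, ignore.case = TRUE)) {
    anno <- rtracklayer::import(path, format = "gtf")
    tx <- anno[as.character(anno$type) == feature_type]
    n_skip <- sum(as.character(GenomicRanges::strand(tx)) == "*")
    if (n_skip) {
      warning(n_skip, " transcript(s) without strand skipped")
      tx <- tx[as.character(GenomicRanges::strand(tx)) != "*"]
    }
    if (!is.null(tag_filter) && !is.na(tag_filter)) {
      if ("tag" %in% names(S4Vectors::mcols(tx))) {
        tags <- tx$tag
        keep <- if (methods::is(tags, "List"))
          any(tags == tag_filter)
        else !is.na(tags) & tags == tag_filter
        tx <- tx[as.logical(keep)]
      } else {
        message("annotation has no 'tag' attribute; retaining all transcripts")
      }
    }
    pts <- GenomicRanges::resize(tx, width = 1L, fix = "start")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty TSS BED file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
      stop(sprintf("malformed BED line %d in %s", which(nf < 3)[1], path))
    chrom <- vapply(fields, `[[`, character(1), 1)
    start0 <- as.integer(vapply(fields, `[[`, character(1), 2))
    strand <- if (all(nf >= 6)) vapply(fields, `[[`, character(1), 6) else "*"
    strand[!strand %in% c("+", "-")] <- "*"
    pts <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(start = start0 + 1L, width = 1L),
                                  strand = strand)
    n_skip <- 0L
  }
  # de-duplicate on exact (chrom, position); first occurrence keeps its strand
  key <- paste0(as.character(GenomicRanges::seqnames(pts)), ":",
                GenomicRanges::start(pts))
  pts <- pts[!duplicated(key)]
  S4Vectors::mcols(pts) <- NULL
  pts <- GenomicRanges::sort(pts, ignore.strand = TRUE)
  attr(pts, "n_skipped_no_strand") <- n_skip
  pts
}
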