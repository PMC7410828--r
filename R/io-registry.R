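#' Write a cCRE registry to disk
#'
#' Emits the registry as a BED-compatible file (chrom, 0-based start, end,
#' rDHS id, cCRE id, group label) plus a companion TSV with the per-assay
#' max-Z values, TSS distance and tier of every element. Rows are stably
#' sorted by (chrom, start, end).
#'
#' @param ccres `GRanges` of cCREs as produced by [build_registry()]
#'   (metadata columns `rdhs_id`, `ccre_id`, `group`, `tier`, `tss_dist`,
#'   `maxz_dnase`, `maxz_h3k4me3`, `maxz_h3k27ac`, `maxz_ctcf`).
#' @param path Output BED path.
#' @param tsv_path Companion TSV path; defaults to `path` with a `.tsv`
#'   extension appended.
#' @return Invisibly, the two paths written.
#' @export
write_registry <- function(ccres, path, tsv_path = paste0(path, ".tsv")) {
  o <- order(as.character(GenomicRanges::seqnames(ccres)),
             GenomicRanges::start(ccres), GenomicRanges::end(ccres))
  ccres <- ccres[o]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ccres)),
    start = GenomicRanges::start(ccres) - 1L,
    end = GenomicRanges::end(ccres),
    rdhs_id = ccres$rdhs_id,
    ccre_id = ccres$ccre_id,
    group = ccres$group,
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write registry BED to ", path, ": ",
                              conditionMessage(e)))
  tsv <- data.frame(
    ccre_id = ccres$ccre_id,
    rdhs_id = ccres$rdhs_id,
    chrom = df$chrom, start = df$start, end = df$end,
    group = ccres$group,
    tier = ccres$tier,
    tss_dist = ccres$tss_dist,
    dnase_maxz = .fmtz(ccres$maxz_dnase),
    h3k4me3_maxz = .fmtz(ccres$maxz_h3k4me3),
    h3k27ac_maxz = .fmtz(ccres$maxz_h3k27ac),
    ctcf_maxz = .fmtz(ccres$maxz_ctcf),
    stringsAsFactors = FALSE)
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(bed = path, tsv = tsv_path))
}

# Deterministic text rendering of Z values ("NA" for unascertained assays)
.fmtz <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Read a registry written by [write_registry()]
#'
#' @param path Registry BED path (the companion TSV is read from
#'   `paste0(path, ".tsv")` when present).
#' @return `GRanges` with the same metadata columns [write_registry()] wrote.
#' @export
read_registry <- function(path, tsv_path = paste0(path, ".tsv")) {
  cols <- c("chrom", "start", "end", "rdhs_id", "ccre_id", "group")
  if (file.size(path) == 0) {
    df <- stats::setNames(data.frame(character(), integer(), integer(),
                                     character(), character(), character()), cols)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = cols, stringsAsFactors = FALSE)
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr)$rdhs_id <- df$rdhs_id
  S4Vectors::mcols(gr)$ccre_id <- df$ccre_id
  S4Vectors::mcols(gr)$group <- df$group
  if (file.exists(tsv_path)) {
    tsv <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "NA",
                             colClasses = c(tier = "character"))
    i <- match(gr$ccre_id, tsv$ccre_id)
    S4Vectors::mcols(gr)$tier <- tsv$tier[i]
    S4Vectors::mcols(gr)$tss_dist <- tsv$tss_dist[i]
    S4Vectors::mcols(gr)$maxz_dnase <- tsv$dnase_maxz[i]
    S4Vectors::mcols(gr)$maxz_h3k4me3 <- tsv$h3k4me3_maxz[i]
    S4Vectors::mcols(gr)$maxz_h3k27ac <- tsv$h3k27ac_maxz[i]
    S4Vectors::mcols(gr)$maxz_ctcf <- tsv$ctcf_maxz[i]
  }
  gr
}
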