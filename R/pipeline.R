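#' Build a cCRE registry from a manifest
#'
#' Runs the full pipeline: read per-biosample DNase peaks, pool and filter
#' them, reduce to non-overlapping rDHSs (optionally filtered against a
#' consensus-DHS set), average each biosample's signal tracks over the
#' rDHSs, Z-score within biosample, reduce to per-assay max-Z, promote
#' rDHSs with high DNase plus at least one high mark to cCREs, classify
#' them (cell-type-agnostic and in every biosample) and assign confidence
#' tiers. Deterministic given the manifest.
#'
#' @param manifest A `ccre_manifest` (see [read_manifest()]) or a path to
#'   one.
#' @return List with:
#'   \describe{
#'     \item{ccres}{`GRanges` of cCREs sorted by coordinate with `rdhs_id`,
#'       `ccre_id`, `group`, `state`, `tss_dist`, `tier` and per-assay
#'       `maxz_*` columns.}
#'     \item{rdhss}{`GRanges` of all rDHSs.}
#'     \item{per_biosample}{data.frame of per-biosample labels, one row per
#'       cCRE, one column per biosample.}
#'     \item{zmatrix}{The `ZScoreMatrix` over all rDHSs.}
#'     \item{report}{Run report (stage counts, parameters, per-biosample QC;
#'       see [write_run_report()]).}
#'   }
#' @export
build_registry <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "ccre_manifest"))
  p <- manifest$parameters
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)

  tss <- extract_tss(manifest$tss, tag_filter = p$tss_tag)

  peaks <- list()
  for (b in manifest$biosamples) {
    if (is.null(b$peaks)) next
    peaks[[b$id]] <- withCallingHandlers(
      read_peaks(b$peaks, format = b$peaks_format, experiment_id = b$id),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  }
  pooled <- if (length(peaks)) do.call(c, unname(peaks)) else .empty_peaks()
  n_input <- length(pooled)

  filtered <- withCallingHandlers(
    filter_dnase_peaks(pooled, signal_floor_pct = p$signal_floor_pct,
                       width_min = p$width_min, width_max = p$width_max,
                       fdr_max = p$fdr_max),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  rdhss <- build_rdhss(filtered)
  n_rdhs <- length(rdhss)

  if (!is.null(manifest$cdhs)) {
    cdhs_gr <- rtracklayer::import(manifest$cdhs, format = "bed")
    rdhss <- withCallingHandlers(
      filter_by_consensus(rdhss, cdhs_gr),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  }
  n_rdhs_cdhs <- length(rdhss)

  tracks <- lapply(manifest$biosamples, function(b) {
    out <- list()
    for (a in intersect(names(b$tracks), core_assays()))
      out[[a]] <- read_signal_track(b$tracks[[a]], assay = a, biosample_id = b$id)
    out
  })
  zm <- withCallingHandlers(
    compute_zscore_matrix(rdhss, tracks, flank_histone = p$flank_histone,
                          zero_sentinel = p$zero_sentinel),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  promoted <- promote_to_ccre(zm, z_threshold = p$z_threshold)
  ccres <- rdhss[promoted]
  zsub <- .subset_zmatrix(zm, promoted)
  d <- tss_distance(ccres, tss)

  thr <- p$z_threshold
  maxz <- zsub$maxz
  high <- function(a) !is.na(maxz[, a]) & maxz[, a] > thr
  group <- classify_agnostic(high("h3k4me3"), high("h3k27ac"), high("ctcf"),
                             d, tss_near = p$tss_near,
                             tss_proximal = p$tss_proximal)
  state <- paste0(ifelse(high("h3k4me3"), "K4+", "K4-"),
                  ifelse(high("h3k27ac"), "K27+", "K27-"),
                  ifelse(high("ctcf"), "CT+", "CT-"))
  tier <- assign_tier(zsub, group, z_threshold = thr)

  keep <- tier != "excluded"
  ccres <- ccres[keep]
  zsub <- .subset_zmatrix(zsub, keep)
  d <- d[keep]; group <- group[keep]; state <- state[keep]; tier <- tier[keep]
  maxz <- zsub$maxz

  S4Vectors::mcols(ccres)$ccre_id <-
    sprintf("%s%07d", p$id_prefix, seq_along(ccres))
  S4Vectors::mcols(ccres)$group <- group
  S4Vectors::mcols(ccres)$state <- state
  S4Vectors::mcols(ccres)$tss_dist <- d
  S4Vectors::mcols(ccres)$tier <- tier
  S4Vectors::mcols(ccres)$maxz_dnase <- maxz[, "dnase"]
  S4Vectors::mcols(ccres)$maxz_h3k4me3 <- maxz[, "h3k4me3"]
  S4Vectors::mcols(ccres)$maxz_h3k27ac <- maxz[, "h3k27ac"]
  S4Vectors::mcols(ccres)$maxz_ctcf <- maxz[, "ctcf"]

  biosample_ids <- rownames(zm$availability)
  per_biosample <- data.frame(ccre_id = ccres$ccre_id,
                              rdhs_id = ccres$rdhs_id,
                              stringsAsFactors = FALSE)
  for (b in biosample_ids) {
    zb <- function(a) if (zm$availability[b, a]) zsub$z[, b, a] else rep(NA_real_, length(ccres))
    per_biosample[[b]] <- classify_biosample(
      zb("dnase"), zb("h3k4me3"), zb("h3k27ac"), zb("ctcf"),
      tss_dist = d, z_threshold = thr,
      tss_near = p$tss_near, tss_proximal = p$tss_proximal)
  }

  report <- list(
    tool = "ccregistry",
    version = as.character(utils::packageVersion("ccregistry")),
    manifest = manifest$path,
    manifest_md5 = unname(tools::md5sum(manifest$path)),
    parameters = p,
    counts = list(
      input_peaks = n_input,
      filtered_peaks = length(filtered),
      rdhss = n_rdhs,
      rdhss_after_cdhs = n_rdhs_cdhs,
      promoted = sum(promoted),
      ccres = length(ccres),
      groups = as.list(table(factor(group, levels = ccre_groups("agnostic")))),
      tiers = as.list(table(factor(tier, levels = c("1a", "1b", "2"))))
    ),
    biosamples = lapply(manifest$biosamples, function(b)
      list(id = b$id, has_peaks = !is.null(b$peaks),
           assays = intersect(names(b$tracks), core_assays()))),
    n_tss = length(tss),
    warnings = warnings_log
  )
  list(ccres = ccres, rdhss = rdhss, per_biosample = per_biosample,
       zmatrix = zm, report = report)
}

.subset_zmatrix <- function(zm, i) {
  structure(list(raw = zm$raw[i, , , drop = FALSE],
                 z = zm$z[i, , , drop = FALSE],
                 maxz = zm$maxz[i, , drop = FALSE],
                 availability = zm$availability,
                 rdhs_id = zm$rdhs_id[i]),
            class = "ZScoreMatrix")
}

#' Write a run report as JSON
#'
#' The report captures per-stage counts, effective parameters, per-biosample
#' assay coverage and accumulated warnings; optionally stamped with the wall
#' clock (off by default so re-runs are byte-identical).
#'
#' @param report Report list from [build_registry()].
#' @param path Output JSON path.
#' @param timestamp Include the current time? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path, timestamp = FALSE) {
  if (timestamp) report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the whole pipeline and write all artifacts
#'
#' Thin orchestration over [build_registry()]: builds the registry and
#' writes, under `out_dir`, the rDHS BED (`rdhs.bed`: chrom, start, end,
#' rdhs_id, winning signal, "."), the registry BED and companion TSV
#' (`registry.bed`, `registry.bed.tsv`), the per-biosample group TSV
#' (`biosample_groups.tsv`), the max-Z TSV over all rDHSs (`maxz.tsv`,
#' "NA" for unascertained assays) and the run report (`report.json`).
#' Two runs on the same manifest produce byte-identical registry files.
#'
#' @param manifest_path Path to the manifest YAML.
#' @param out_dir Output directory (created if needed).
#' @param timestamp Stamp the report with the wall clock?
#' @return The [build_registry()] result, invisibly, with `$paths` added.
#' @export
run_all <- function(manifest_path, out_dir, timestamp = FALSE) {
  res <- build_registry(manifest_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    rdhs = file.path(out_dir, "rdhs.bed"),
    registry = file.path(out_dir, "registry.bed"),
    registry_tsv = file.path(out_dir, "registry.bed.tsv"),
    biosample_groups = file.path(out_dir, "biosample_groups.tsv"),
    maxz = file.path(out_dir, "maxz.tsv"),
    report = file.path(out_dir, "report.json"))

  r <- res$rdhss
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(r)),
               GenomicRanges::start(r) - 1L, GenomicRanges::end(r),
               r$rdhs_id, sprintf("%.6g", r$signal), "."),
    paths["rdhs"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  write_registry(res$ccres, paths["registry"], paths["registry_tsv"])
  utils::write.table(res$per_biosample, paths["biosample_groups"],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mz <- res$zmatrix$maxz
  utils::write.table(
    data.frame(rdhs_id = res$zmatrix$rdhs_id,
               dnase_maxz = .fmtz(mz[, "dnase"]),
               h3k4me3_maxz = .fmtz(mz[, "h3k4me3"]),
               h3k27ac_maxz = .fmtz(mz[, "h3k27ac"]),
               ctcf_maxz = .fmtz(mz[, "ctcf"])),
    paths["maxz"], sep = "\t", quote = FALSE, row.names = FALSE)

  write_run_report(res$report, paths["report"], timestamp = timestamp)
  res$paths <- paths
  invisible(res)
}
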