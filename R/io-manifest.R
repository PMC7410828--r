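#' Read and validate a run manifest
#'
#' The manifest (YAML) declares the inputs of a registry build: one entry per
#' biosample with its DNase peak file and whichever of the four core assay
#' signal tracks it has, a TSS annotation, an optional consensus-DHS BED, and
#' parameter overrides. Relative paths are resolved against the manifest's
#' directory. Which assays a biosample has is inferred from the tracks it
#' declares; that availability governs the classification scheme and tier
#' logic downstream.
#'
#' Expected layout:
#' ```yaml
#' genome: toy
#' tss: tss.bed            # or a .gtf
#' cdhs: cdhs.bed          # optional; omit to disable consensus filtering
#' parameters: { z_threshold: 1.64 }   # optional overrides
#' biosamples:
#'   - id: B1
#'     peaks: B1.peaks.narrowPeak      # optional if the biosample lacks DNase
#'     tracks:
#'       dnase: B1.dnase.bedGraph
#'       h3k4me3: B1.h3k4me3.bedGraph
#' ```
#'
#' @param path Path to the manifest YAML.
#' @return A `ccre_manifest` list with elements `genome`, `tss`, `cdhs`,
#'   `parameters` (merged over [default_parameters()]), `biosamples`, and
#'   `dir`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest does not exist: ", path)
  raw <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(dir, p)
  }
  if (is.null(raw$biosamples) || !length(raw$biosamples))
    stop("manifest declares no biosamples")

  biosamples <- lapply(raw$biosamples, function(b) {
    if (is.null(b$id)) stop("manifest biosample without an 'id'")
    tracks <- lapply(b$tracks, resolve)
    bad <- setdiff(names(tracks), core_assays())
    if (length(bad))
      stop("biosample ", b$id, ": unknown assay(s) in tracks: ",
           paste(bad, collapse = ", "))
    list(id = b$id, peaks = resolve(b$peaks),
         peaks_format = if (is.null(b$peaks_format)) "narrowPeak" else b$peaks_format,
         tracks = tracks)
  })
  ids <- vapply(biosamples, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate biosample ids in manifest")
  names(biosamples) <- ids

  m <- structure(list(
    genome = if (is.null(raw$genome)) "unknown" else raw$genome,
    tss = resolve(raw$tss),
    cdhs = resolve(raw$cdhs),
    parameters = merge_parameters(raw$parameters),
    biosamples = biosamples,
    dir = dir,
    path = normalizePath(path)
  ), class = "ccre_manifest")
  validate_manifest(m)
  m
}

#' Validate a manifest
#'
#' Checks that every referenced file exists and that each biosample has at
#' least one assay. Called automatically by [read_manifest()].
#'
#' @param m A `ccre_manifest`.
#' @return The manifest, invisibly; errors name the biosample and assay at
#'   fault.
#' @export
validate_manifest <- function(m) {
  stopifnot(inherits(m, "ccre_manifest"))
  if (is.null(m$tss)) stop("manifest must declare a 'tss' annotation")
  if (!file.exists(m$tss)) stop("TSS annotation not found: ", m$tss)
  if (!is.null(m$cdhs) && !file.exists(m$cdhs))
    stop("consensus-DHS file not found: ", m$cdhs)
  for (b in m$biosamples) {
    if (!length(b$tracks))
      stop("biosample ", b$id, " declares no assays")
    for (assay in names(b$tracks)) {
      if (!file.exists(b$tracks[[assay]]))
        stop("biosample ", b$id, ", assay ", assay,
             ": signal track not found: ", b$tracks[[assay]])
    }
    if (!is.null(b$peaks) && !file.exists(b$peaks))
      stop("biosample ", b$id, ": peak file not found: ", b$peaks)
    if (is.null(b$tracks$dnase) && is.null(b$peaks) &&
        !length(intersect(names(b$tracks), core_assays()[-1])))
      stop("biosample ", b$id, " has neither DNase nor any ChIP assay")
  }
  invisible(m)
}

#' Assay availability matrix of a manifest
#'
#' @param m A `ccre_manifest`.
#' @return Logical matrix, biosamples x the four core assays: `TRUE` where
#'   the biosample declares a signal track for the assay.
#' @export
manifest_availability <- function(m) {
  stopifnot(inherits(m, "ccre_manifest"))
  ids <- names(m$biosamples)
  av <- matrix(FALSE, nrow = length(ids), ncol = 4,
               dimnames = list(ids, core_assays()))
  for (b in m$biosamples)
    av[b$id, intersect(names(b$tracks), core_assays())] <- TRUE
  av
}

#' @export
print.ccre_manifest <- function(x, ...) {
  av <- manifest_availability(x)
  cat(sprintf("ccre_manifest: genome=%s, %d biosample(s)\n", x$genome, nrow(av)))
  cat(sprintf("  assays per biosample: %s\n",
              paste(sprintf("%s[%s]", rownames(av),
                            apply(av, 1, function(r) paste(substr(colnames(av)[r], 1, 2), collapse = ","))),
                    collapse = " ")))
  invisible(x)
}
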