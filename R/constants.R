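#' Core assay names
#'
#' The four assays the registry is built from, in canonical order. DNase-seq
#' measures chromatin accessibility; H3K4me3 and H3K27ac ChIP-seq mark
#' promoter- and enhancer-associated chromatin; CTCF ChIP-seq marks candidate
#' insulator/looping sites.
#'
#' @return Character vector of assay identifiers.
#' @export
core_assays <- function() c("dnase", "h3k4me3", "h3k27ac", "ctcf")

# Display names used in reports and per-biosample mark-flag labels
.assay_display <- c(dnase = "DNase", h3k4me3 = "H3K4me3",
                    h3k27ac = "H3K27ac", ctcf = "CTCF")

#' cCRE group labels
#'
#' @param context `"agnostic"` for the five cell-type-agnostic groups,
#'   `"biosample"` for the seven groups reachable in a biosample fully covered
#'   by the four core assays.
#' @return Character vector of group labels.
#' @export
ccre_groups <- function(context = c("agnostic", "biosample")) {
  context <- match.arg(context)
  agnostic <- c("PLS", "pELS", "dELS", "DNase-H3K4me3", "CTCF-only")
  if (context == "agnostic") agnostic
  else c(agnostic, "DNase-only", "low-DNase")
}

#' Default pipeline parameters
#'
#' All tunable thresholds of the registry pipeline with their default values:
#' \describe{
#'   \item{z_threshold}{High-signal cutoff on Z and max-Z scores (1.64, the
#'     one-sided standard-normal 95th percentile; "high" means strictly
#'     greater).}
#'   \item{signal_floor_pct}{Percentile (over the pooled signals of all DNase
#'     peaks) below which peaks are discarded (10).}
#'   \item{width_min,width_max}{Retained DNase peak widths, bp (150, 350).}
#'   \item{fdr_max}{Peaks with FDR at or above this are discarded (1e-3,
#'     strict \code{<}).}
#'   \item{tss_near,tss_proximal}{TSS distance bands, bp: centre-to-TSS
#'     distance <= 200 is TSS-overlapping, (200, 2000] proximal,
#'     > 2000 distal.}
#'   \item{flank_histone}{Flank added on each side of an rDHS when averaging
#'     H3K4me3/H3K27ac signal, bp (500); DNase and CTCF use 0.}
#'   \item{zero_sentinel}{Z-score assigned to rDHSs with raw signal 0 (-10).}
#'   \item{tss_tag}{GTF transcript tag retained when extracting TSSs
#'     ("basic").}
#'   \item{id_prefix}{Accession prefix for emitted cCRE identifiers.}
#' }
#'
#' @return Named list of parameter defaults.
#' @export
default_parameters <- function() {
  list(
    z_threshold      = 1.64,
    signal_floor_pct = 10,
    width_min        = 150L,
    width_max        = 350L,
    fdr_max          = 1e-3,
    tss_near         = 200,
    tss_proximal     = 2000,
    flank_histone    = 500L,
    zero_sentinel    = -10,
    tss_tag          = "basic",
    id_prefix        = "SYNCRE"
  )
}

# Merge user parameters over defaults, validating documented ranges.
merge_parameters <- function(params = list()) {
  p <- default_parameters()
  if (length(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  stopifnot(
    is.numeric(p$z_threshold),
    p$signal_floor_pct >= 0, p$signal_floor_pct <= 100,
    p$width_min > 0, p$width_max >= p$width_min,
    p$fdr_max > 0, p$fdr_max <= 1,
    p$tss_near >= 0, p$tss_proximal >= p$tss_near,
    p$flank_histone >= 0
  )
  p
}

# Flank (bp) used when averaging signal for an assay: histone marks spread to
# flanking nucleosomes, so their windows are extended; DNase and CTCF are not.
assay_flank <- function(assay, flank_histone = 500L) {
  ifelse(assay %in% c("h3k4me3", "h3k27ac"), as.integer(flank_histone), 0L)
}
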