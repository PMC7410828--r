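#' Distance from element centre to the nearest TSS
#'
#' For each interval, returns the minimum over all TSS points of the absolute
#' genomic distance between the interval's centre and the TSS position,
#' strand-agnostic. Centres use the 0-based convention
#' `floor((start0 + end0) / 2)`. Intervals on a chromosome with no TSS get
#' `Inf` (treated as TSS-distal downstream).
#'
#' @param regions `GRanges` of rDHSs/cCREs.
#' @param tss `GRanges` of width-1 TSS points (see [extract_tss()]).
#' @return Numeric vector of distances in bp.
#' @export
tss_distance <- function(regions, tss) {
  if (!length(tss)) stop("empty TSS set: classification impossible")
  n <- length(regions)
  out <- rep(Inf, n)
  if (!n) return(out)
  centre0 <- floor((GenomicRanges::start(regions) - 1 +
                    GenomicRanges::end(regions)) / 2)
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  tchrom <- as.character(GenomicRanges::seqnames(tss))
  tpos0 <- GenomicRanges::start(tss) - 1
  for (ch in unique(rchrom)) {
    idx <- which(rchrom == ch)
    pos <- sort(tpos0[tchrom == ch])
    if (!length(pos)) next
    # nearest sorted point via findInterval: compare the flanking candidates
    i <- findInterval(centre0[idx], pos)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(pos))
    out[idx] <- pmin(abs(centre0[idx] - pos[lo]), abs(centre0[idx] - pos[hi]))
  }
  out
}

#' Promote rDHSs to cCREs
#'
#' An rDHS becomes a cCRE when its DNase max-Z is high (strictly above the
#' threshold) AND at least one of the three ChIP marks (H3K4me3, H3K27ac,
#' CTCF) also has a high max-Z. DNase-only rDHSs are not cCREs.
#'
#' @param maxz rDHS x assay max-Z matrix (columns named as [core_assays()]),
#'   or a `ZScoreMatrix`.
#' @param z_threshold High-signal cutoff (default 1.64; strict `>`).
#' @return Logical vector, one entry per rDHS.
#' @export
promote_to_ccre <- function(maxz, z_threshold = 1.64) {
  if (inherits(maxz, "ZScoreMatrix")) maxz <- maxz$maxz
  if (is.null(dim(maxz))) maxz <- matrix(maxz, nrow = 1,
                                         dimnames = list(NULL, names(maxz)))
  if (anyNA(maxz[, "dnase"]))
    stop("DNase max-Z unascertained for some rDHSs: cannot promote")
  high <- function(a) !is.na(maxz[, a]) & maxz[, a] > z_threshold
  high("dnase") & (high("h3k4me3") | high("h3k27ac") | high("ctcf"))
}

# Shared decision table over high/low mark flags and TSS distance.
# `biosample_mode` adds the DNase-only fallback; in agnostic mode reaching
# the final branch without a high mark is an internal error (promotion
# guarantees at least one high mark).
.classify_table <- function(hk4, hk27, hct, d, tss_near, tss_proximal,
                            biosample_mode = FALSE) {
  n <- length(d)
  out <- character(n)
  pls <- d <= tss_near & hk4
  els <- !pls & hk27 & (d > tss_proximal | !hk4)
  dk4 <- !pls & !els & hk4
  ct  <- !pls & !els & !dk4 & hct
  out[pls] <- "PLS"
  out[els] <- ifelse(d[els] <= tss_proximal, "pELS", "dELS")
  out[dk4] <- "DNase-H3K4me3"
  out[ct] <- "CTCF-only"
  rest <- !(pls | els | dk4 | ct)
  if (any(rest)) {
    if (!biosample_mode)
      stop("internal error: promoted element with no high mark")
    out[rest] <- "DNase-only"
  }
  out
}

#' Cell-type-agnostic cCRE classification
#'
#' Assigns each promoted element exactly one of the five agnostic groups
#' from its max-Z high/low state and the distance from its centre to the
#' nearest TSS, via the priority decision table:
#' \enumerate{
#'   \item PLS: within `tss_near` bp of a TSS and high H3K4me3;
#'   \item pELS/dELS: high H3K27ac and (beyond `tss_proximal` bp, or low
#'     H3K4me3); proximal at distance `<= tss_proximal`, else distal;
#'   \item DNase-H3K4me3: high H3K4me3 (beyond `tss_near` bp of a TSS);
#'   \item CTCF-only: high CTCF with the above all ruled out.
#' }
#' Promoter identity dominates: an element within `tss_near` bp of a TSS
#' with high H3K4me3 is PLS whatever its other marks — the only precedence
#' under which the five groups are mutually exclusive and exhaustive over
#' the seven promotable states.
#'
#' @param high_h3k4me3,high_h3k27ac,high_ctcf Logical vectors of mark
#'   high-flags (max-Z > threshold). Unascertained marks should be passed
#'   as `FALSE` here only if absent from every biosample (they can then
#'   never support a call).
#' @param tss_dist Distances from [tss_distance()].
#' @param tss_near,tss_proximal Band boundaries in bp (defaults 200 and
#'   2000; both bands inclusive of their upper bound).
#' @return Character vector of group labels.
#' @export
classify_agnostic <- function(high_h3k4me3, high_h3k27ac, high_ctcf,
                              tss_dist, tss_near = 200, tss_proximal = 2000) {
  hk4 <- !is.na(high_h3k4me3) & high_h3k4me3
  hk27 <- !is.na(high_h3k27ac) & high_h3k27ac
  hct <- !is.na(high_ctcf) & high_ctcf
  if (any(!(hk4 | hk27 | hct)))
    stop("classify_agnostic called on an element with no high mark (not promotable)")
  .classify_table(hk4, hk27, hct, tss_dist, tss_near, tss_proximal,
                  biosample_mode = FALSE)
}

#' Per-biosample cCRE classification
#'
#' Classifies cCREs within one biosample from that biosample's own Z-scores,
#' with fallbacks for missing assays (pass `NA` for an assay the biosample
#' lacks):
#' \itemize{
#'   \item DNase present, Z low: `"low-DNase"` regardless of the marks;
#'   \item DNase high: the agnostic decision table over the available marks
#'     (a missing mark can never support a call, so e.g. lacking H3K27ac
#'     makes pELS/dELS unreachable), with `"DNase-only"` when no available
#'     mark is high;
#'   \item DNase missing: no positional group is assignable; elements with
#'     at least one high available mark get a mark-flag label
#'     (`"high-H3K4me3"`, `"high-H3K27ac+CTCF"`, ...), and elements with all
#'     available marks low are `"unclassified"`.
#' }
#'
#' @param z_dnase,z_h3k4me3,z_h3k27ac,z_ctcf Numeric vectors of
#'   within-biosample Z-scores; `NA` = assay not available in this
#'   biosample.
#' @param tss_dist Distances from [tss_distance()].
#' @param z_threshold High cutoff (default 1.64, strict `>`).
#' @param tss_near,tss_proximal Band boundaries in bp.
#' @return Character vector of labels.
#' @export
classify_biosample <- function(z_dnase, z_h3k4me3, z_h3k27ac, z_ctcf,
                               tss_dist, z_threshold = 1.64,
                               tss_near = 200, tss_proximal = 2000) {
  n <- length(tss_dist)
  hk4 <- !is.na(z_h3k4me3) & z_h3k4me3 > z_threshold
  hk27 <- !is.na(z_h3k27ac) & z_h3k27ac > z_threshold
  hct <- !is.na(z_ctcf) & z_ctcf > z_threshold
  out <- character(n)

  no_dnase <- is.na(z_dnase)
  if (any(no_dnase)) {
    idx <- which(no_dnase)
    flags <- cbind(hk4[idx], hk27[idx], hct[idx])
    lab <- apply(flags, 1, function(f) {
      if (!any(f)) "unclassified"
      else paste0("high-", paste(.assay_display[c("h3k4me3", "h3k27ac", "ctcf")][f],
                                 collapse = "+"))
    })
    out[idx] <- lab
  }
  low <- !no_dnase & z_dnase <= z_threshold
  out[low] <- "low-DNase"
  hi <- !no_dnase & !low
  if (any(hi))
    out[hi] <- .classify_table(hk4[hi], hk27[hi], hct[hi], tss_dist[hi],
                               tss_near, tss_proximal, biosample_mode = TRUE)
  out
}

# Mark whose high max-Z drove each agnostic group call
.pertinent_marks <- c(PLS = "h3k4me3", pELS = "h3k27ac", dELS = "h3k27ac",
                      `DNase-H3K4me3` = "h3k4me3", `CTCF-only` = "ctcf")

#' Assign confidence tiers
#'
#' Tiers record how directly the data support each cCRE call, based on the
#' pertinent mark of its agnostic group (H3K4me3 for PLS and DNase-H3K4me3,
#' H3K27ac for pELS/dELS, CTCF for CTCF-only):
#' \describe{
#'   \item{1a}{some biosample covered by all four assays has high DNase and
#'     a high pertinent mark concordantly;}
#'   \item{1b}{some biosample (possibly missing other assays) has high DNase
#'     and a high pertinent mark concordantly;}
#'   \item{2}{high DNase and the high pertinent mark occur only in different
#'     biosamples, so concordance could not be tested;}
#'   \item{excluded}{no supporting combination at all (such elements are
#'     dropped from the registry).}
#' }
#' Adding assay data can only promote a tier (2 to 1b to 1a), never demote
#' it.
#'
#' @param zm `ZScoreMatrix` over the cCREs being tiered (rows aligned with
#'   `group`).
#' @param group Agnostic group label per cCRE.
#' @param z_threshold High cutoff (default 1.64).
#' @return Character vector of tiers (`"1a"`, `"1b"`, `"2"`, `"excluded"`).
#' @export
assign_tier <- function(zm, group, z_threshold = 1.64) {
  stopifnot(inherits(zm, "ZScoreMatrix"))
  n <- dim(zm$z)[1]
  stopifnot(length(group) == n)
  zh <- zm$z > z_threshold          # NA where assay missing
  full <- rowSums(zm$availability) == 4L
  pert <- .pertinent_marks[group]
  if (anyNA(pert)) stop("unknown group label: ",
                        paste(unique(group[is.na(pert)]), collapse = ", "))
  vapply(seq_len(n), function(i) {
    m <- pert[i]
    conc <- zh[i, , "dnase"] & zh[i, , m]
    conc[is.na(conc)] <- FALSE
    if (any(conc & full)) return("1a")
    if (any(conc)) return("1b")
    d_any <- any(zh[i, , "dnase"], na.rm = TRUE)
    m_any <- any(zh[i, , m], na.rm = TRUE)
    if (d_any && m_any) "2" else "excluded"
  }, character(1))
}
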