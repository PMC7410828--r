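#' Configuration for the synthetic registry generator
#'
#' Describes a toy genome with planted regulatory elements of known class,
#' used to benchmark every pipeline stage against ground truth. Elements are
#' placed on an evenly spaced grid of slots (so that signal windows never
#' collide) and each class's TSS is planted at the offset that makes its
#' truth label consistent with the distance bands: 0 bp for PLS, 1000 bp for
#' pELS and DNase-H3K4me3, 4000 bp for dELS and CTCF-only, none for inert
#' elements.
#'
#' Background signal is lognormal: log10 of the per-locus signal is drawn
#' from Normal(`background_log_mean`, `background_log_sd`) independently per
#' locus, biosample and assay. Planted elements multiply the background by
#' `effect_size` for the marks their class carries (DNase for every
#' non-inert class, H3K4me3 for PLS and DNase-H3K4me3, H3K27ac for
#' pELS/dELS, CTCF for CTCF-only). ChIP marks at unbound loci additionally
#' have zero coverage with probability `mark_zero_prob`, exercising the
#' zero-signal sentinel. Decoy DNase peaks at background signal are placed
#' at rate `decoy_rate` per bp; they keep the planted fraction of each
#' Z-score vector small, as in a real registry where most rDHSs are inactive
#' for any given mark.
#'
#' @param genome_name,genome_length Toy chromosome name and length (bp).
#' @param n_per_class Named counts of planted elements per class
#'   (`PLS`, `pELS`, `dELS`, `DNase-H3K4me3`, `CTCF-only`, `inert`).
#' @param n_extra_tss Decoy TSSs planted away from all elements.
#' @param biosample_ids Biosample identifiers.
#' @param availability Logical biosample x assay matrix; `NULL` means all
#'   four assays in every biosample.
#' @param background_log_mean,background_log_sd Mean and sd of log10
#'   background signal.
#' @param effect_size Multiplicative elevation over background for active
#'   (class, mark) pairs; a scalar, or a class x assay matrix.
#' @param width_range Planted element and decoy widths (bp), kept inside the
#'   peak width filter so planted elements survive filtering by
#'   construction.
#' @param decoy_rate Decoy peaks per bp (Poisson).
#' @param mark_zero_prob Probability a ChIP mark has zero coverage at a
#'   locus where it is not elevated.
#' @param peak_jitter Maximum per-biosample shift (bp) of a peak around its
#'   element.
#' @param seed Default RNG seed for [simulate_registry_inputs()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_name = "chrS",
                       genome_length = 2000000L,
                       n_per_class = c(PLS = 10L, pELS = 10L, dELS = 10L,
                                       `DNase-H3K4me3` = 10L,
                                       `CTCF-only` = 10L, inert = 10L),
                       n_extra_tss = 20L,
                       biosample_ids = paste0("B", 1:4),
                       availability = NULL,
                       background_log_mean = 0,
                       background_log_sd = 0.3,
                       effect_size = 8,
                       width_range = c(150L, 350L),
                       decoy_rate = 2.5e-4,
                       mark_zero_prob = 0.35,
                       peak_jitter = 20L,
                       seed = 1L) {
  classes <- c("PLS", "pELS", "dELS", "DNase-H3K4me3", "CTCF-only", "inert")
  full <- stats::setNames(rep(0L, length(classes)), classes)
  full[names(n_per_class)] <- as.integer(n_per_class)
  if (is.null(availability))
    availability <- matrix(TRUE, length(biosample_ids), 4,
                           dimnames = list(biosample_ids, core_assays()))
  stopifnot(all(rownames(availability) == biosample_ids),
            all(colnames(availability) == core_assays()),
            all(full >= 0), genome_length > 0,
            width_range[1] <= width_range[2],
            background_log_sd >= 0, all(effect_size >= 1),
            mark_zero_prob >= 0, mark_zero_prob < 1)
  structure(list(genome_name = genome_name,
                 genome_length = as.integer(genome_length),
                 n_per_class = full, n_extra_tss = as.integer(n_extra_tss),
                 biosample_ids = biosample_ids, availability = availability,
                 background_log_mean = background_log_mean,
                 background_log_sd = background_log_sd,
                 effect_size = effect_size,
                 width_range = as.integer(width_range),
                 decoy_rate = decoy_rate,
                 mark_zero_prob = mark_zero_prob,
                 peak_jitter = as.integer(peak_jitter),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# TSS offset (bp from element centre) making each class's distance band hold
.class_tss_offset <- c(PLS = 0, pELS = 1000, dELS = 4000,
                       `DNase-H3K4me3` = 1000, `CTCF-only` = 4000,
                       inert = NA)

# Which assays each class elevates
.class_marks <- list(
  PLS = c("dnase", "h3k4me3"),
  pELS = c("dnase", "h3k27ac"),
  dELS = c("dnase", "h3k27ac"),
  `DNase-H3K4me3` = c("dnase", "h3k4me3"),
  `CTCF-only` = c("dnase", "ctcf"),
  inert = character(0))

.effect_for <- function(config, class, assay) {
  e <- config$effect_size
  if (is.matrix(e)) e[class, assay] else e
}

# Signal rectangles must not overlap within a bedGraph, so loci need
# clearance of twice the largest pad (histone pad 650) plus one.
.PAD_POINT <- 50L      # DNase/CTCF rectangles: covers peak jitter
.PAD_HISTONE <- 650L   # histone rectangles: covers the 500-bp flank + jitter
.MIN_GAP <- 1400L      # minimum edge-to-edge gap between simulated loci

#' Generate synthetic registry inputs
#'
#' Writes, under `out_dir`, everything a registry build needs: one
#' narrowPeak file per biosample with DNase data (peaks at every planted
#' element and decoy, jittered per biosample), one bedGraph per available
#' (biosample, assay), a TSS BED, a `truth.tsv` of planted elements,
#' a `decoys.bed`, and a ready-to-run `manifest.yaml`. Given the same
#' config and seed the outputs are byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return Invisibly, a list with `manifest` (path), `truth` (data.frame:
#'   `element_id`, `chrom`, `start`, `end` (0-based half-open), `class`,
#'   `tss_pos`), `decoys` (data.frame), and `dir`.
#' @export
simulate_registry_inputs <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  L <- config$genome_length
  chrom <- config$genome_name

  spacing <- 12000L
  slots <- seq(10000L, L - 10000L, by = spacing)
  n_elem <- sum(config$n_per_class)
  need <- n_elem + config$n_extra_tss
  if (length(slots) < need)
    stop("genome too small: ", need, " slots needed, ", length(slots),
         " available; increase genome_length")
  slots <- sample(slots)   # shuffle so class is independent of position

  classes <- rep(names(config$n_per_class), config$n_per_class)
  widths <- if (n_elem)
    sample(seq(config$width_range[1], config$width_range[2]), n_elem,
           replace = TRUE) else integer(0)
  centre <- slots[seq_len(n_elem)]
  start0 <- centre - widths %/% 2L
  end0 <- start0 + widths
  truth <- data.frame(
    element_id = sprintf("EL%04d", seq_len(n_elem)),
    chrom = rep(chrom, n_elem), start = start0, end = end0,
    class = classes,
    tss_pos = centre + .class_tss_offset[classes],
    stringsAsFactors = FALSE)

  extra_tss <- if (config$n_extra_tss)
    slots[n_elem + seq_len(config$n_extra_tss)] else integer(0)
  tss_pos <- sort(c(truth$tss_pos[!is.na(truth$tss_pos)], extra_tss))
  tss_pos <- unique(tss_pos)

  # Poisson-placed decoys, thinned to respect the no-overlap clearance
  n_decoy <- stats::rpois(1, config$decoy_rate * L)
  dec_centre <- sort(as.integer(round(stats::runif(n_decoy, 5000, L - 5000))))
  dec_w <- if (n_decoy)
    sample(seq(config$width_range[1], config$width_range[2]), n_decoy,
           replace = TRUE) else integer(0)
  keep <- logical(n_decoy)
  last_end <- -Inf
  elem_sorted <- sort(centre)
  for (i in seq_len(n_decoy)) {
    s <- dec_centre[i] - dec_w[i] %/% 2L
    e <- s + dec_w[i]
    near_elem <- length(elem_sorted) &&
      min(abs(elem_sorted - dec_centre[i])) < 2500
    if (!near_elem && s - last_end >= .MIN_GAP) {
      keep[i] <- TRUE
      last_end <- e
    }
  }
  decoys <- data.frame(
    decoy_id = sprintf("DC%04d", seq_len(sum(keep))),
    chrom = rep(chrom, sum(keep)),
    start = (dec_centre - dec_w %/% 2L)[keep],
    end = (dec_centre - dec_w %/% 2L + dec_w)[keep],
    stringsAsFactors = FALSE)

  # All simulated loci, elements first, in genome order within each table
  loci <- rbind(
    data.frame(id = truth$element_id, start = truth$start, end = truth$end,
               class = truth$class, stringsAsFactors = FALSE),
    data.frame(id = decoys$decoy_id, start = decoys$start, end = decoys$end,
               class = "decoy", stringsAsFactors = FALSE))
  n_loci <- nrow(loci)

  paths <- list()
  write_bedgraph <- function(df, path) {
    df <- df[order(df$start), ]
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, df$start, df$end,
                       sprintf("%.6g", df$value)), path)
  }

  dnase_values <- list()  # per biosample, reused for peak signalValue
  for (b in config$biosample_ids) {
    for (a in core_assays()) {
      if (!config$availability[b, a]) next
      base <- 10^stats::rnorm(n_loci, config$background_log_mean,
                              config$background_log_sd)
      elevated <- vapply(seq_len(n_loci), function(i)
        a %in% .class_marks[[loci$class[i]]] %||% FALSE, logical(1))
      value <- base
      if (any(elevated))
        value[elevated] <- base[elevated] *
          vapply(which(elevated), function(i)
            .effect_for(config, loci$class[i], a), numeric(1))
      covered <- rep(TRUE, n_loci)
      if (a != "dnase")
        covered[!elevated] <- stats::runif(sum(!elevated)) >= config$mark_zero_prob
      pad <- if (a %in% c("h3k4me3", "h3k27ac")) .PAD_HISTONE else .PAD_POINT
      df <- data.frame(start = pmax(loci$start - pad, 0L),
                       end = pmin(loci$end + pad, L),
                       value = value)[covered, ]
      path <- file.path(out_dir, sprintf("%s.%s.bedGraph", b, a))
      write_bedgraph(df, path)
      paths[[paste(b, a, sep = ".")]] <- path
      if (a == "dnase") dnase_values[[b]] <- value
    }
    if (config$availability[b, "dnase"]) {
      shift <- sample(seq(-config$peak_jitter, config$peak_jitter), n_loci,
                      replace = TRUE)
      qval <- ifelse(loci$class %in% c("decoy", "inert"), 5, 6)
      o <- order(loci$start + shift)
      pk <- file.path(out_dir, sprintf("%s.peaks.narrowPeak", b))
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t%s\t-1",
                         chrom, (loci$start + shift)[o], (loci$end + shift)[o],
                         paste0(b, "_", loci$id)[o],
                         sprintf("%.6g", dnase_values[[b]])[o],
                         sprintf("%.6g", qval)[o]),
                 pk)
      paths[[paste0(b, ".peaks")]] <- pk
    }
  }

  tss_path <- file.path(out_dir, "tss.bed")
  writeLines(sprintf("%s\t%d\t%d\tTSS%04d\t0\t+", chrom, tss_pos,
                     tss_pos + 1L, seq_along(tss_pos)), tss_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  decoy_path <- file.path(out_dir, "decoys.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", decoys$chrom, decoys$start,
                     decoys$end, decoys$decoy_id), decoy_path)

  manifest <- list(
    genome = config$genome_name,
    tss = "tss.bed",
    biosamples = lapply(config$biosample_ids, function(b) {
      tracks <- list()
      for (a in core_assays())
        if (config$availability[b, a])
          tracks[[a]] <- sprintf("%s.%s.bedGraph", b, a)
      out <- list(id = b, tracks = tracks)
      if (config$availability[b, "dnase"])
        out$peaks <- sprintf("%s.peaks.narrowPeak", b)
      out
    }))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(manifest = manifest_path, truth = truth, decoys = decoys,
                 dir = out_dir, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score recovery of planted elements
#'
#' A planted element counts as recovered when some cCRE's centre lies within
#' the element's interval AND the cCRE carries the element's truth class;
#' label matching is exact (a dELS recovered as pELS is a miss for dELS and
#' a false positive for pELS). Precision per class is the fraction of
#' predicted cCREs of that class whose centre lies inside a truth element of
#' the same class.
#'
#' @param ccres cCRE `GRanges` from [build_registry()] (with a `group`
#'   column).
#' @param truth Truth table from [simulate_registry_inputs()].
#' @return data.frame with one row per non-inert class: `class`, `n_truth`,
#'   `n_pred`, `recall`, `precision` (`NA` when the class has no
#'   predictions).
#' @export
score_recovery <- function(ccres, truth) {
  classes <- c("PLS", "pELS", "dELS", "DNase-H3K4me3", "CTCF-only")
  centre0 <- if (length(ccres))
    floor((GenomicRanges::start(ccres) - 1 + GenomicRanges::end(ccres)) / 2)
  else numeric(0)
  cchrom <- as.character(GenomicRanges::seqnames(ccres))
  group <- if (length(ccres)) ccres$group else character(0)
  hit_class <- function(g) {
    tr <- truth[truth$class == g, , drop = FALSE]
    pred <- which(group == g)
    inside <- function(row) any(cchrom[pred] == tr$chrom[row] &
                                centre0[pred] >= tr$start[row] &
                                centre0[pred] < tr$end[row])
    recovered <- if (nrow(tr)) vapply(seq_len(nrow(tr)), inside, logical(1))
                 else logical(0)
    tp <- if (length(pred)) vapply(pred, function(i)
      any(tr$chrom == cchrom[i] & centre0[i] >= tr$start &
          centre0[i] < tr$end), logical(1)) else logical(0)
    data.frame(class = g, n_truth = nrow(tr), n_pred = length(pred),
               recall = if (nrow(tr)) mean(recovered) else NA_real_,
               precision = if (length(pred)) mean(tp) else NA_real_,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(classes, hit_class))
}
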