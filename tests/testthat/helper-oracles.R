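# Shared fixtures and independent oracles.
# Coordinates in tests are written BED-style (0-based half-open) and
# converted here at the boundary, mirroring how files enter the package.

library(GenomicRanges)

gr0 <- function(start0, end0, chrom = "chr1") {
  GRanges(rep_len(chrom, length(start0)),
          IRanges::IRanges(start0 + 1L, end0))
}

peaks0 <- function(start0, end0, signal, fdr = 1e-6,
                   experiment_id = "E1", chrom = "chr1") {
  gr <- gr0(start0, end0, chrom)
  mcols(gr)$name <- sprintf("p%d", seq_along(gr))
  mcols(gr)$signal <- signal
  mcols(gr)$fdr <- rep_len(fdr, length(gr))
  mcols(gr)$experiment_id <- rep_len(experiment_id, length(gr))
  gr
}

# Brute-force greedy rDHS oracle: re-sorts the full remaining peak set every
# iteration and tests overlap by direct coordinate comparison. Returns the
# indices of winning peaks in selection order.
brute_greedy <- function(peaks) {
  chrom <- as.character(seqnames(peaks))
  s <- start(peaks); e <- end(peaks)
  sig <- peaks$signal
  eid <- if (is.null(peaks$experiment_id)) rep("", length(peaks)) else peaks$experiment_id
  remaining <- seq_along(peaks)
  winners <- integer(0)
  removed <- list()   # peaks each winner absorbed when selected
  while (length(remaining)) {
    o <- order(-sig[remaining], chrom[remaining], s[remaining],
               e[remaining], eid[remaining])
    w <- remaining[o[1]]
    winners <- c(winners, w)
    ov <- chrom[remaining] == chrom[w] &
      s[remaining] <= e[w] & e[remaining] >= s[w]
    removed[[length(winners)]] <- remaining[ov]
    remaining <- remaining[!ov]
  }
  structure(winners, removed = removed)
}

# Random peak instance for oracle-equivalence checks
random_peak_instance <- function(n_max = 50) {
  n <- sample(1:n_max, 1)
  s0 <- sample(0:2000, n, replace = TRUE)
  w <- sample(50:400, n, replace = TRUE)
  peaks0(s0, s0 + w,
         signal = round(stats::runif(n, 0, 20), 3),
         experiment_id = sample(c("E1", "E2", "E3"), n, replace = TRUE),
         chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
}

# Per-base-pair mean oracle for signal averaging over a piecewise track.
# segments: data.frame(start0, end0, value); window [s0, e0) clipped at 0.
brute_mean <- function(segments, s0, e0) {
  s0 <- max(s0, 0)
  pos <- seq(s0, e0 - 1)
  val <- vapply(pos, function(p) {
    hit <- segments$start0 <= p & p < segments$end0
    if (any(hit)) segments$value[which(hit)[1]] else 0
  }, numeric(1))
  sum(val) / (e0 - s0)
}

# Hand-written truth table for the cell-type-agnostic classifier:
# all 7 promotable mark combinations x 3 distance bands
# (A: d <= 200, B: 200 < d <= 2000, C: d > 2000). Derived from the group
# definitions with promoter identity taking precedence.
agnostic_truth_table <- function() {
  tab <- rbind(
    c(1, 0, 0, "A", "PLS"), c(1, 0, 0, "B", "DNase-H3K4me3"), c(1, 0, 0, "C", "DNase-H3K4me3"),
    c(0, 1, 0, "A", "pELS"), c(0, 1, 0, "B", "pELS"), c(0, 1, 0, "C", "dELS"),
    c(0, 0, 1, "A", "CTCF-only"), c(0, 0, 1, "B", "CTCF-only"), c(0, 0, 1, "C", "CTCF-only"),
    c(1, 1, 0, "A", "PLS"), c(1, 1, 0, "B", "DNase-H3K4me3"), c(1, 1, 0, "C", "dELS"),
    c(1, 0, 1, "A", "PLS"), c(1, 0, 1, "B", "DNase-H3K4me3"), c(1, 0, 1, "C", "DNase-H3K4me3"),
    c(0, 1, 1, "A", "pELS"), c(0, 1, 1, "B", "pELS"), c(0, 1, 1, "C", "dELS"),
    c(1, 1, 1, "A", "PLS"), c(1, 1, 1, "B", "DNase-H3K4me3"), c(1, 1, 1, "C", "dELS"))
  data.frame(k4 = as.logical(as.integer(tab[, 1])),
             k27 = as.logical(as.integer(tab[, 2])),
             ct = as.logical(as.integer(tab[, 3])),
             band = tab[, 4], label = tab[, 5], stringsAsFactors = FALSE)
}

# Representative in-band distances used when enumerating the tables
band_distance <- c(A = 100, B = 1000, C = 5000)

# Hand-written truth table for the fully-covered biosample classifier:
# the low-DNase state (regardless of marks) plus the 8 high-DNase states
# across the 3 distance bands. The 7 promotable states follow the agnostic
# table; the all-low state is DNase-only in every band.
biosample_truth_table <- function() {
  ag <- agnostic_truth_table()
  ag$dnase <- TRUE
  only <- data.frame(k4 = FALSE, k27 = FALSE, ct = FALSE,
                     band = c("A", "B", "C"), label = "DNase-only",
                     dnase = TRUE, stringsAsFactors = FALSE)
  low <- expand.grid(k4 = c(TRUE, FALSE), k27 = c(TRUE, FALSE),
                     ct = c(TRUE, FALSE), band = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  low$label <- "low-DNase"
  low$dnase <- FALSE
  rbind(ag, only, low)
}

# High/low flags to Z values clearly on either side of the 1.64 cutoff
zval <- function(high) ifelse(high, 3, 0.2)

write_lines <- function(lines, path) { writeLines(lines, path); path }
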