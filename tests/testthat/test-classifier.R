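test_that("TSS distance is the strand-agnostic minimum from the element centre", {
  tss1 <- gr0(1100, 1101)
  expect_equal(tss_distance(gr0(1000, 1200), tss1), 0)
  expect_equal(tss_distance(gr0(1000, 1200), gr0(1300, 1301)), 200)
  # brute-force min over several points
  tss <- c(gr0(500, 501), gr0(3000, 3001))
  expect_equal(tss_distance(gr0(1000, 1200), tss), 600)
  # no TSS on the element's chromosome: distal
  expect_equal(tss_distance(gr0(0, 200, "chr9"), tss1), Inf)
  expect_error(tss_distance(gr0(0, 200), GRanges()), "empty TSS")
})

test_that("promotion needs high DNase plus at least one high mark, strictly", {
  mz <- function(d, k4 = 0, k27 = 0, ct = 0)
    matrix(c(d, k4, k27, ct), 1,
           dimnames = list(NULL, c("dnase", "h3k4me3", "h3k27ac", "ctcf")))
  expect_false(promote_to_ccre(mz(2.0)))              # DNase-only
  expect_false(promote_to_ccre(mz(1.64, k4 = 3)))    # boundary is not high
  expect_true(promote_to_ccre(mz(2.0, ct = 1.65)))
  expect_false(promote_to_ccre(mz(1.0, k4 = 5)))
  expect_error(promote_to_ccre(mz(NA, k4 = 3)), "unascertained")
  # an epsilon across the threshold flips the call
  eps <- 1e-9
  expect_true(promote_to_ccre(mz(1.64 + eps, k4 = 1.64 + eps)))
})

test_that("agnostic classification matches the hand-written 21-row truth table", {
  tab <- agnostic_truth_table()
  d <- band_distance[tab$band]
  got <- classify_agnostic(tab$k4, tab$k27, tab$ct, d)
  expect_equal(got, tab$label)
  # worked examples at the band boundaries: both bands include their bound
  expect_equal(classify_agnostic(TRUE, FALSE, FALSE, 150), "PLS")
  expect_equal(classify_agnostic(TRUE, FALSE, FALSE, 200), "PLS")
  expect_equal(classify_agnostic(FALSE, TRUE, FALSE, 900), "pELS")
  expect_equal(classify_agnostic(FALSE, TRUE, FALSE, 2000), "pELS")
  expect_equal(classify_agnostic(FALSE, TRUE, FALSE, 5000), "dELS")
  expect_equal(classify_agnostic(FALSE, FALSE, TRUE, 5000), "CTCF-only")
  expect_error(classify_agnostic(FALSE, FALSE, FALSE, 100), "not promotable")
})

test_that("every promotable state in every band gets exactly one of the 5 groups", {
  combos <- expand.grid(k4 = c(TRUE, FALSE), k27 = c(TRUE, FALSE),
                        ct = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  for (dd in c(0, 100, 200, 201, 1500, 2000, 2001, 1e5)) {
    lab <- classify_agnostic(combos$k4, combos$k27, combos$ct, rep(dd, 7))
    expect_true(all(lab %in% ccre_groups("agnostic")))
    expect_length(lab, 7)
  }
})

test_that("biosample classification matches its truth table and missing-assay rules", {
  tab <- biosample_truth_table()
  d <- band_distance[tab$band]
  got <- classify_biosample(zval(tab$dnase), zval(tab$k4), zval(tab$k27),
                            zval(tab$ct), d)
  expect_equal(got, tab$label)

  # low DNase regardless of marks; DNase-only when all marks low
  expect_equal(classify_biosample(1.0, 5, 5, 5, 100), "low-DNase")
  expect_equal(classify_biosample(2.0, 0, 0, 0, 100), "DNase-only")

  # lacking H3K27ac: PLS and DNase-H3K4me3 reachable, pELS/dELS not
  expect_equal(classify_biosample(2, 3, NA, 0.2, 100), "PLS")
  expect_equal(classify_biosample(2, 3, NA, 0.2, 1000), "DNase-H3K4me3")
  combos <- expand.grid(k4 = c(3, 0.2), ct = c(3, 0.2),
                        d = unname(band_distance))
  lab27 <- classify_biosample(rep(2, nrow(combos)), combos$k4,
                              rep(NA_real_, nrow(combos)), combos$ct, combos$d)
  expect_false(any(lab27 %in% c("pELS", "dELS")))

  # lacking DNase: mark flags only; all-low is unclassified
  expect_equal(classify_biosample(NA, 0.2, 0.2, 0.2, 100), "unclassified")
  expect_equal(classify_biosample(NA, 3, 0.2, 0.2, 100), "high-H3K4me3")
  expect_equal(classify_biosample(NA, 0.2, 3, 3, 100), "high-H3K27ac+CTCF")
})

test_that("tiers reflect concordance and assay completeness, monotonically", {
  mk_zm <- function(z, availability) {
    n <- dim(z)[1]
    structure(list(raw = z, z = z,
                   maxz = suppressWarnings(apply(z, c(1, 3), max, na.rm = TRUE)),
                   availability = availability,
                   rdhs_id = sprintf("R%d", seq_len(n))),
              class = "ZScoreMatrix")
  }
  assays <- c("dnase", "h3k4me3", "h3k27ac", "ctcf")
  av_full <- matrix(TRUE, 2, 4, dimnames = list(c("X", "Y"), assays))

  # concordant high DNase + high H3K27ac in a fully-covered biosample: 1a
  z <- array(0.2, c(1, 2, 4), dimnames = list("R1", c("X", "Y"), assays))
  z[1, "X", "dnase"] <- 3; z[1, "X", "h3k27ac"] <- 3
  expect_equal(assign_tier(mk_zm(z, av_full), "dELS"), "1a")

  # same signals but biosample X has only DNase and CTCF: the pertinent
  # H3K27ac support comes from partially covered X via... here make X
  # partially covered with DNase+H3K27ac: concordant but incomplete -> 1b
  av_part <- av_full; av_part["X", c("h3k4me3", "ctcf")] <- FALSE
  z2 <- z; z2[1, , "h3k4me3"] <- NA; z2[1, "X", "ctcf"] <- NA
  expect_equal(assign_tier(mk_zm(z2, av_part), "dELS"), "1b")

  # high DNase only in X (which lacks H3K4me3), high H3K4me3 only in Y
  # (which lacks DNase): support in different biosamples -> tier 2
  av2 <- av_full; av2["X", "h3k4me3"] <- FALSE; av2["Y", "dnase"] <- FALSE
  z3 <- array(0.2, c(1, 2, 4), dimnames = list("R1", c("X", "Y"), assays))
  z3[1, "X", "dnase"] <- 3; z3[1, "X", "h3k4me3"] <- NA
  z3[1, "Y", "dnase"] <- NA; z3[1, "Y", "h3k4me3"] <- 3
  expect_equal(assign_tier(mk_zm(z3, av2), "PLS"), "2")

  # adding the missing assays with high signal promotes 2 -> 1a, never demotes
  z4 <- z3; z4[1, "X", "h3k4me3"] <- 3
  expect_equal(assign_tier(mk_zm(z4, av_full), "PLS"), "1a")

  # pertinent mark drives tiering: CTCF-only ignores concordant H3K4me3
  z5 <- array(0.2, c(1, 2, 4), dimnames = list("R1", c("X", "Y"), assays))
  z5[1, "X", "dnase"] <- 3; z5[1, "X", "h3k4me3"] <- 3
  z5[1, "Y", "ctcf"] <- 3
  expect_equal(assign_tier(mk_zm(z5, av_full), "CTCF-only"), "2")
})
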