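test_that("BED6+ peaks read back with exact widths and order", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_lines(c("chr1\t0\t200\ta\t0\t.\t5.0",
                "chr1\t500\t700\tb\t0\t.\t2.0",
                "chr2\t10\t310\tc\t0\t.\t9.0"), path)
  pk <- read_peaks(path, format = "bed6+", experiment_id = "E9")
  expect_length(pk, 3)
  expect_equal(width(pk), c(200L, 200L, 300L))
  expect_equal(pk$name, c("a", "b", "c"))
  expect_equal(pk$signal, c(5, 2, 9))
  expect_true(all(is.na(pk$fdr)))
  expect_equal(unique(pk$experiment_id), "E9")
  # 0-based half-open converted, never leaked inward
  expect_equal(start(pk)[1], 1L)
  expect_equal(end(pk)[1], 200L)
})

test_that("narrowPeak qValue is decoded as -log10 FDR", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  write_lines(c("chr1\t100\t300\tp1\t0\t.\t7.5\t-1\t3.0\t50",
                "chr1\t400\t600\tp2\t0\t.\t1.0\t-1\t-1\t50"), path)
  pk <- read_peaks(path, format = "narrowPeak")
  expect_equal(pk$signal[1], 7.5)
  expect_equal(pk$fdr[1], 1e-3)
  expect_true(is.na(pk$fdr[2]))  # qValue -1 means unavailable
})

test_that("empty peak files give an empty result, malformed lines name the line", {
  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_length(read_peaks(empty, format = "bed6+"), 0)

  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  write_lines(c("chr1\t100\t300\tp1\t0\t.\t7.5\t-1\t3.0\t50",
                "chr1\t400\t600\tp2"), bad)
  expect_error(read_peaks(bad, format = "narrowPeak"), "line 2")

  nonnum <- withr::local_tempfile(fileext = ".bed")
  write_lines("chr1\t0\t200\ta\t0\t.\tnot_a_number", nonnum)
  expect_error(read_peaks(nonnum, format = "bed6+"), "line 1")
})

test_that("bedGraph tracks are queryable piecewise-constant coverage", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_lines("chr1\t0\t100\t2.0", path)
  tr <- read_signal_track(path, "dnase", "B1")
  expect_equal(average_signal(tr, gr0(0, 100)), 2.0)
  expect_equal(average_signal(tr, gr0(20, 60)), 2.0)
  # queries beyond the covered span read 0
  expect_equal(average_signal(tr, gr0(5000, 5100)), 0)
})

test_that("averaging straddles record boundaries with per-bp weights", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_lines(c("chr1\t0\t100\t1.0", "chr1\t100\t200\t3.0"), path)
  tr <- read_signal_track(path, "dnase", "B1")
  expect_equal(average_signal(tr, gr0(50, 150)), 2.0)
})

test_that("overlapping bedGraph records are rejected", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_lines(c("chr1\t0\t100\t1.0", "chr1\t50\t150\t3.0"), path)
  expect_error(read_signal_track(path), "overlap")
})

test_that("TSS extraction follows strand and de-duplicates shared 5' ends", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "%s"; tag "basic";'
  write_lines(c(
    sprintf("chr1\thavana\ttranscript\t1001\t2000\t.\t+\t.\t%s", sprintf(attrs, "t1")),
    sprintf("chr1\thavana\ttranscript\t1001\t2000\t.\t-\t.\t%s", sprintf(attrs, "t2")),
    sprintf("chr1\thavana\ttranscript\t1001\t3000\t.\t+\t.\t%s", sprintf(attrs, "t3")),
    sprintf("chr1\thavana\ttranscript\t5001\t6000\t.\t+\t.\t%s",
            'gene_id "g2"; transcript_id "t4";'),
    sprintf("chr1\thavana\texon\t1001\t1200\t.\t+\t.\t%s", sprintf(attrs, "t1"))),
    gtf)
  tss <- extract_tss(gtf, tag_filter = "basic")
  # + strand 5' end at 0-based 1000; - strand at 0-based 1999 (last base);
  # t3 shares t1's 5' end and collapses; t4 lacks the basic tag
  expect_equal(start(tss) - 1L, c(1000L, 1999L))
  expect_length(tss, 2)
})

test_that("TSS extraction accepts point BED and honours the tag filter default off", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_lines(c(
    "chr1\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id \"g\"; transcript_id \"a\";",
    "chr1\tx\ttranscript\t301\t400\t.\t+\t.\tgene_id \"g\"; transcript_id \"b\";"),
    gtf)
  expect_message(tss <- extract_tss(gtf, tag_filter = "basic"), "no 'tag'")
  expect_length(tss, 2)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_lines(c("chr1\t999\t1000\tT1\t0\t-", "chr1\t50\t51\tT2\t0\t+"), bed)
  pts <- extract_tss(bed)
  expect_equal(start(pts) - 1L, c(50L, 999L))
  expect_equal(as.character(strand(pts)), c("+", "-"))
})

test_that("registry write/read round-trips and sorts by coordinate", {
  gr <- c(gr0(500, 700, "chr1"), gr0(0, 200, "chr1"))
  mcols(gr)$rdhs_id <- c("RDHS000002", "RDHS000001")
  mcols(gr)$ccre_id <- c("SYNCRE0000002", "SYNCRE0000001")
  mcols(gr)$group <- c("dELS", "PLS")
  mcols(gr)$tier <- c("1a", "2")
  mcols(gr)$tss_dist <- c(2600, 100)
  mcols(gr)$maxz_dnase <- c(2.5, 3.1)
  mcols(gr)$maxz_h3k4me3 <- c(0.2, 4.0)
  mcols(gr)$maxz_h3k27ac <- c(2.2, 0.5)
  mcols(gr)$maxz_ctcf <- c(NA_real_, NA_real_)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_registry(gr, bed)
  lines <- readLines(bed)
  expect_equal(length(lines), 2)
  expect_equal(strsplit(lines[1], "\t")[[1]][c(2, 6)], c("0", "PLS"))

  back <- read_registry(bed)
  expect_equal(start(back) - 1L, c(0L, 500L))
  expect_equal(back$group, c("PLS", "dELS"))
  expect_equal(back$tier, c("2", "1a"))
  expect_equal(back$maxz_h3k4me3, c(4.0, 0.2))
  expect_true(all(is.na(back$maxz_ctcf)))
})

test_that("manifest validation names the missing biosample and assay", {
  d <- withr::local_tempdir()
  write_lines("chr1\t0\t100\t1.0", file.path(d, "B1.dnase.bedGraph"))
  write_lines("chr1\t0\t1\tT\t0\t+", file.path(d, "tss.bed"))
  yaml::write_yaml(list(
    genome = "toy", tss = "tss.bed",
    biosamples = list(list(id = "B1", tracks = list(
      dnase = "B1.dnase.bedGraph", h3k4me3 = "missing.bedGraph")))),
    file.path(d, "manifest.yaml"))
  expect_error(read_manifest(file.path(d, "manifest.yaml")), "B1.*h3k4me3")

  yaml::write_yaml(list(
    genome = "toy", tss = "tss.bed",
    biosamples = list(list(id = "B1", tracks = list(dnase = "B1.dnase.bedGraph")))),
    file.path(d, "manifest.yaml"))
  m <- read_manifest(file.path(d, "manifest.yaml"))
  av <- manifest_availability(m)
  expect_true(av["B1", "dnase"])
  expect_false(any(av["B1", c("h3k4me3", "h3k27ac", "ctcf")]))
})
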