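# Capture profiling: interval calling, partition bookkeeping, subgenome
# specificity and polymorphism rates.

test_that("captured intervals are maximal runs at the depth threshold", {
  iv <- capturedIntervals(c(0, 12, 12, 9, 15))
  expect_equal(IRanges::start(iv), c(2L, 5L))
  expect_equal(IRanges::end(iv), c(3L, 5L))
  expect_equal(length(capturedIntervals(rep(0, 50))), 0)
  iv <- capturedIntervals(rep(11, 40))
  expect_equal(as.integer(c(IRanges::start(iv), IRanges::end(iv))),
               c(1L, 40L))
  # threshold is configurable
  expect_equal(length(capturedIntervals(c(5, 5, 5), min_depth = 5)), 1)
})

test_that("partition lengths split capture into promoter/5'UTR/exon-intron", {
  win <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 3300))
  parts <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(1001, 2466, 2701, 3001), c(2465, 2700, 3000, 3300)),
    part = c("promoter", "five_utr", "exon", "exon"))
  # full target capture only
  d <- c(rep(20L, 1700), rep(0L, 600))
  pl <- partitionLengths(capturedIntervals(d), d, win, parts)
  expect_equal(pl$promoter_bp, 1465L)
  expect_equal(pl$five_utr_bp, 235L)
  expect_equal(pl$target_bp, 1700L)
  expect_equal(pl$exon_intron_bp, 0L)
  expect_equal(pl$max_depth, 20L)
  # capture extending 300 bp into exon 1
  d2 <- c(rep(20L, 2000), rep(0L, 300))
  pl2 <- partitionLengths(capturedIntervals(d2), d2, win, parts)
  expect_equal(pl2$exon_intron_bp, 300L)
  expect_equal(pl2$total_bp, 2000L)
  # no capture at all
  d3 <- rep(0L, 2300)
  pl3 <- partitionLengths(capturedIntervals(d3), d3, win, parts)
  expect_equal(pl3$total_bp, 0L)
})

test_that("partition lengths conserve captured basepairs", {
  set.seed(12)
  win <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 500))
  parts <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(c(1, 301, 401), c(300, 400, 500)),
    part = c("promoter", "five_utr", "exon"))
  for (k in 1:20) {
    d <- sample(c(0L, 15L), 500, replace = TRUE)
    iv <- capturedIntervals(d)
    pl <- partitionLengths(iv, d, win, parts)
    expect_equal(pl$total_bp, sum(IRanges::width(iv)))
  }
})

test_that("subgenome fractions and verdicts follow the expected patterns", {
  mk <- function(sub, bp) data.frame(subgenome = sub, target_bp = bp)
  s <- mk(rep(c("A", "B", "D"), each = 10), rep(1700, 30))
  fr <- subgenomeCaptureFractions(s, expected = c("A", "B", "D"))
  expect_equal(unname(fr$percent_by_count), c(33.3, 33.3, 33.3))
  expect_equal(sum(fr$percent_by_bases), 100, tolerance = 0.1)
  expect_equal(fr$verdict, "pass")
  # tetraploid AABB: no D capture
  s2 <- mk(rep(c("A", "B", "D"), each = 10),
           c(rep(1700, 20), rep(0, 10)))
  fr2 <- subgenomeCaptureFractions(s2, expected = c("A", "B"))
  expect_equal(unname(fr2$percent_by_count[["D"]]), 0)
  expect_equal(fr2$observed, c("A", "B"))
  expect_equal(fr2$verdict, "pass")
  # observed presence outside the expectation warns
  fr3 <- subgenomeCaptureFractions(s, expected = c("A", "B"))
  expect_equal(fr3$verdict, "warn")
  # nothing captured warns too
  fr4 <- subgenomeCaptureFractions(mk("A", 0), expected = "A")
  expect_equal(fr4$verdict, "warn")
})

test_that("expected patterns map compositions through relatedness", {
  expect_equal(expectedPattern(c("A", "A", "B", "B", "D", "D")),
               c("A", "B", "D"))
  expect_equal(expectedPattern(c("A", "A", "B", "B")), c("A", "B"))
  expect_equal(expectedPattern(c("D", "D")), "D")
  expect_equal(expectedPattern("Am,Am"), "A")
  expect_equal(expectedPattern(c("S", "S")), "B")
  expect_error(expectedPattern(c("Z", "Z")), "unknown")
  expect_equal(expectedPattern(c("Z", "Z"), relatedness = c(Z = "B")), "B")
})

test_that("polymorphism frequency is per kbp with one decimal", {
  expect_equal(polymorphismFrequency(10, 5000), 2.0)
  expect_equal(polymorphismFrequency(0, 5000), 0.0)
  expect_equal(polymorphismFrequency(814, 908 * 1494), 0.6)
  # linear scaling leaves the rate unchanged
  expect_equal(polymorphismFrequency(2 * 814, 2 * 908 * 1494), 0.6)
  expect_error(polymorphismFrequency(1, 0), "positive")
})

test_that("reference self-check is zero on the synthetic panel", {
  p <- smallPanel()
  sc <- p$report$self_check
  expect_equal(sc$n_targets_with_snps, 0L)
  expect_equal(sc$n_snps, 0L)
})

test_that("reference self-check counts targets and mean SNPs per promoter", {
  dummy <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 2001), c(1700, 3700)),
    strand = "+", gene_id = c("g1", "g2"), trait_tag = "T1-1",
    homoeo_group_id = c("H1", "H2"), subgenome = "A",
    atg_pos = c(1701L, 3701L), arm = "1AS")
  ts <- new("TargetSet", targets = dummy,
            partitions = GenomicRanges::GRangesList())
  v <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                  ref = "A", alt = "T", vtype = "SNP", indel_len = 0L,
                  af = 1, qual = 60, depth = 30L)
  sc <- referenceSelfCheck(v, ts)
  expect_equal(sc$n_targets_with_snps, 1L)
  expect_equal(sc$n_snps, 3L)
  expect_equal(sc$percent_targets, 50)
  # the printed-arithmetic convention: 814 SNPs over 908 promoters -> 0.9
  expect_equal(roundHalfAway(814 / 908, 1), 0.9)
})

test_that("capture summaries on the panel sum subgenome percents to 100", {
  p <- smallPanel()
  sg <- p$report$subgenome
  for (a in unique(sg$accession_id)) {
    s <- sg[sg$accession_id == a, ]
    if (sum(s$n_captured) == 0) next
    expect_equal(sum(s$percent_by_bases), 100, tolerance = 0.1,
                 label = a)
  }
})
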