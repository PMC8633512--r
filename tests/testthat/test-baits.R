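# Bait design workflow: tiling geometry, masking, specificity screening and
# filtering.

test_that("candidate tiling follows the closed form", {
  cand <- tileCandidates(1, 1700)
  expect_equal(nrow(cand), 27)
  expect_equal(cand$start, seq(1, 1561, by = 60))
  expect_true(all(cand$end - cand$start + 1 == 120))
  expect_equal(nrow(tileCandidates(1, 120)), 1)
  expect_equal(nrow(tileCandidates(1, 854)), 13)  # minimum reduced target
  expect_error(tileCandidates(1, 119), "shorter")
})

test_that("candidate count matches floor((L-120)/60)+1 across spans", {
  for (span in seq(120, 5000, by = 7)) {
    expect_equal(nrow(tileCandidates(1, span)),
                 floor((span - 120) / 60) + 1,
                 label = paste("span", span))
  }
})

test_that("masked fraction is overlap over probe length", {
  probes <- data.frame(probe_id = "p1", gene_id = "g", chrom = "c",
                       start = 101L, end = 220L, sequence = strrep("A", 120),
                       masked_fraction = NA_real_, hyb_hits = NA_integer_,
                       status = NA_character_)
  mk <- function(s, e) list(c = IRanges::IRanges(s, e))
  expect_equal(probeMaskedFraction(probes, mk(191, 400))$masked_fraction,
               0.25)
  expect_equal(probeMaskedFraction(probes, mk(500, 600))$masked_fraction, 0)
  expect_equal(probeMaskedFraction(probes, mk(1, 400))$masked_fraction, 1)
})

test_that("probe filtering applies mask-first then multi-hit rules", {
  base <- data.frame(probe_id = paste0("p", 1:3), gene_id = "g",
                     chrom = "c", start = c(1L, 121L, 241L),
                     end = c(120L, 240L, 360L),
                     sequence = strrep("A", 120),
                     masked_fraction = c(0.25, 0.10, 0.10),
                     hyb_hits = c(1L, 3L, 1L),
                     status = NA_character_)
  ps <- filterProbes(base)
  expect_equal(probeTable(ps)$status,
               c("removed_masked", "removed_multihit", "retained"))
  # idempotent and order-independent
  again <- filterProbes(probeTable(ps))
  expect_equal(probeTable(again)$status, probeTable(ps)$status)
  shuffled <- filterProbes(base[c(3, 1, 2), ])
  expect_equal(probeTable(shuffled)$status,
               c("retained", "removed_masked", "removed_multihit"))
  expect_error(filterProbes(transform(base, hyb_hits = NA)), "populated")
})

test_that("repeat masking marks planted copies in both orientations", {
  set.seed(31)
  el <- randomSeq(300)
  left <- randomSeq(500); mid <- randomSeq(400); right <- randomSeq(500)
  chrom <- paste0(left, el, mid, oracleRevcomp(el), right)
  genome <- Biostrings::DNAStringSet(c(chr = chrom))
  lib <- Biostrings::DNAStringSet(c(rep1 = el))
  mt <- maskRepeats(genome, lib)
  expect_equal(length(mt$chr), 2)
  expect_equal(IRanges::start(mt$chr), c(501L, 1201L))
  expect_equal(IRanges::end(mt$chr), c(800L, 1500L))

  # element shorter than min_match_len never masks
  mtShort <- maskRepeats(genome, Biostrings::DNAStringSet(c(s = "ACGTACGT")))
  expect_equal(length(mtShort$chr), 0)
  expect_warning(maskRepeats(genome, Biostrings::DNAStringSet()), "empty")
})

test_that("specificity screen counts strong sites like the exhaustive oracle", {
  set.seed(77)
  probe <- randomSeq(120)
  # probe at its own locus, one verbatim copy on another chromosome, and one
  # homoeologous copy diverged beyond the identity threshold
  diverged <- strsplit(probe, "")[[1]]
  idx <- seq(2, 120, by = 6)  # ~17% divergence
  diverged[idx] <- vapply(diverged[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  chrA <- paste0(randomSeq(300), probe, randomSeq(300))
  chrB <- paste0(randomSeq(250), probe, randomSeq(350))
  chrC <- paste0(randomSeq(200), paste(diverged, collapse = ""),
                 randomSeq(400))
  g1 <- Biostrings::DNAStringSet(c(chrA = chrA))
  g2 <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB))
  g3 <- Biostrings::DNAStringSet(c(chrA = chrA, chrC = chrC))
  expect_equal(specificityScreen(probe, g1), 1L)
  expect_equal(specificityScreen(probe, g2), 2L)
  expect_equal(specificityScreen(probe, g3), 1L)
  # oracle agreement on the three-chromosome genome
  gAll <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB, chrC = chrC))
  expect_equal(specificityScreen(probe, gAll),
               oracleHybSites(probe, as.character(gAll)))
})

test_that("target coverage reports union bp and rounded percent", {
  mkProbes <- function(starts) {
    n <- length(starts)
    filterProbes(data.frame(
      probe_id = paste0("p", seq_len(n)), gene_id = "g", chrom = "c",
      start = starts, end = starts + 119L, sequence = strrep("A", 120),
      masked_fraction = 0, hyb_hits = 1L, status = NA_character_))
  }
  # 8 disjoint 120 bp probes on a 1700 bp target
  tc <- targetCoverage(mkProbes(seq(1, by = 200, length.out = 8)), 1, 1700,
                       "g")
  expect_equal(tc$covered_bp, 960L)
  expect_equal(tc$percent, 56.5)
  # full 27-probe start-anchored tiling covers 1680 of 1700 bp (the last
  # start is 1561, so the final 20 bp beyond 1680 carry no probe)
  tc <- targetCoverage(mkProbes(seq(1, 1561, by = 60)), 1, 1700, "g")
  expect_equal(tc$covered_bp, 1680L)
  expect_equal(tc$percent, 98.8)
  # a tiling with an extra end-anchored probe reaches 100%
  tc <- targetCoverage(mkProbes(c(seq(1, 1561, by = 60), 1581)), 1, 1700,
                       "g")
  expect_equal(tc$percent, 100)
  # nothing retained
  removed <- probeTable(mkProbes(1))
  removed$status <- "removed_masked"
  tc <- targetCoverage(removed, 1, 1700, "g")
  expect_equal(tc$covered_bp, 0L)
  expect_equal(tc$percent, 0)
})

test_that("probes inside the planted TE are mask-removed on the panel", {
  p <- smallPanel()
  te <- simTruth(p$sim)$te
  pt <- probeTable(p$probes)
  inTE <- pt$chrom == te$chrom & pt$start >= te$start - 90 &
    pt$end <= te$end + 90
  expect_true(any(inTE))
  expect_true(all(pt$status[inTE] == "removed_masked"))
  # and every retained probe is genome-wide unique at the screen thresholds
  expect_true(all(pt$hyb_hits[pt$status == "retained"] == 1))
})
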