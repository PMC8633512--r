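# TFBS scanning: exact IUPAC matching, species dedup, SNP-window gain/loss
# and deletion motif content.

motifFile <- function() {
  system.file("extdata", "plant_motifs_example.tsv", package = "promcap")
}

test_that("motif loading validates IUPAC and collapses species duplicates", {
  lib <- loadMotifs(motifFile())
  mt <- motifTable(lib)
  expect_false(any(duplicated(paste(mt$name, mt$consensus))))
  wbox <- mt[mt$name == "W-box", ]
  expect_equal(nrow(wbox), 1)
  expect_match(wbox$species, ";")          # two species collapsed into one
  expect_equal(nchar(mt$consensus[mt$name == "TTGATC-motif"]), 6)

  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  write.table(data.frame(name = "X", species = "sp", consensus = "TTGAXC"),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadMotifs(bad), "row")
})

test_that("scan finds exact matches on both strands and never through N", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.tsv")
  write.table(data.frame(name = c("m6", "m4"), species = "sp",
                         consensus = c("TTGATC", "TGAC")),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  lib <- loadMotifs(f)
  h <- scanMotifs("ATTGATCA", lib)
  h6 <- h[h$name == "m6", ]
  expect_equal(nrow(h6), 1)
  expect_equal(h6$start, 2)
  expect_equal(h6$strand, "+")
  # TGAC on both strands of TGACGTCA: forward at 1, revcomp(TGAC)=GTCA at 5
  h2 <- scanMotifs("TGACGTCA", lib)
  h4 <- h2[h2$name == "m4", ]
  expect_equal(h4$start[h4$strand == "+"], 1)
  expect_equal(h4$start[h4$strand == "-"], 5)
  # N blocks matching
  expect_equal(nrow(scanMotifs("ATTGANCA", lib)), 0)
  # empty library: no hits
  empty <- loadMotifs(f)
  empty@motifs <- empty@motifs[0, ]
  expect_equal(nrow(scanMotifs("ATTGATCA", empty)), 0)
})

test_that("scan equals the brute-force enumeration on random sequences", {
  lib <- loadMotifs(motifFile())
  mt <- motifTable(lib)
  set.seed(909)
  for (k in 1:60) {
    s <- randomSeq(sample(30:200, 1))
    got <- scanMotifs(s, lib)
    want <- oracleScan(s, mt)
    expect_equal(nrow(got), nrow(want), label = s)
    if (nrow(want)) {
      expect_equal(got[, c("name", "start", "end")],
                   want[, c("name", "start", "end")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  lib <- loadMotifs(motifFile())
  set.seed(910)
  for (k in 1:10) {
    s <- randomSeq(120)
    fwd <- scanMotifs(s, lib)
    rev <- scanMotifs(oracleRevcomp(s), lib)
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd)) {
      n <- nchar(s)
      mirrored <- sort(n - fwd$end + 1L)
      expect_equal(sort(rev$start), mirrored)
    }
  }
})

test_that("species-row duplication does not change deduped hit counts", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "one.tsv"); f2 <- file.path(dir, "two.tsv")
  write.table(data.frame(name = "m", species = "spA", consensus = "TGAC"),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(name = c("m", "m"), species = c("spA", "spB"),
                         consensus = "TGAC"),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- "TTGACTTTGACT"
  expect_equal(nrow(scanMotifs(s, loadMotifs(f1))),
               nrow(scanMotifs(s, loadMotifs(f2))))
})

test_that("a promoter SNP can lose one site and gain another", {
  # the classic resistance-gene case: the SNP at [-143] destroys the
  # TTGATC motif and creates a W-box
  lib <- loadMotifs(motifFile())
  refSeq <- paste0("GGCAG", "ATTGATCAAAG", "CCTTG")
  # SNP at the T (position 11 of refSeq): TTGATC -> TTGACC (= W-box TTGACY)
  delta <- snpWindowDelta(refSeq, 11, "C", lib)
  expect_equal(delta$lost, "TTGATC-motif")
  expect_equal(delta$gained, "W-box")
  expect_equal(length(delta$lost), 1)
  expect_equal(length(delta$gained), 1)
})

test_that("SNP windows with no motifs give an empty delta", {
  lib <- loadMotifs(motifFile())
  delta <- snpWindowDelta("CCCCCCCCCCCCCCC", 8, "G", lib)
  expect_equal(length(delta$gained), 0)
  expect_equal(length(delta$lost), 0)
  # degenerate ref = alt: identical windows, empty delta
  s <- randomSeq(31)
  b <- substring(s, 16, 16)
  d2 <- snpWindowDelta(s, 16, b, lib)
  expect_equal(length(d2$gained), 0)
  expect_equal(length(d2$lost), 0)
})

test_that("windows truncate at sequence boundaries instead of shifting", {
  lib <- loadMotifs(motifFile())
  d <- snpWindowDelta("ACGTACGTAC", 2, "T", lib)
  expect_equal(d$window, c(1, 7))
})

test_that("deletion TFBS content counts deduped sites, zero allowed", {
  lib <- loadMotifs(motifFile())
  span <- paste0("AATTGACCAA", "AGATAAGAA", "ACACGTGAA")
  res <- deletionTfbsContent(span, lib)
  expect_gte(res$count, 3)
  expect_true(all(c("W-box", "I-box", "G-box") %in% res$hits$name))
  expect_equal(deletionTfbsContent("CCCCCCCC", lib)$count, 0)
  expect_equal(deletionTfbsContent("", lib)$count, 0)
})
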