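# Structural variants: cliff-edge gaps, repeat/chimera annotation, hairpins
# and genome hit counting.

test_that("cliff deletions respect the length floor and window edges", {
  # 19 zeros: below the 21 bp minimum
  d <- c(20, 20, rep(0, 19), 20, 20)
  res <- detectCliffDeletions(d)
  expect_equal(nrow(res$deletions), 0)
  # 30 zeros with deep flanks: one event with exact breakpoints
  d <- c(rep(15, 10), rep(0, 30), rep(12, 10))
  res <- detectCliffDeletions(d)
  expect_equal(res$deletions$start, 11)
  expect_equal(res$deletions$end, 40)
  expect_equal(res$deletions$size, 30)
  expect_equal(res$deletions$class, "mid")
  # zeros running to the window end: truncated, not a deletion
  d <- c(rep(15, 10), rep(0, 40))
  res <- detectCliffDeletions(d)
  expect_equal(nrow(res$deletions), 0)
  expect_equal(res$truncated$size, 40)
  # shallow flank (below flank_depth) blocks the call
  d <- c(rep(5, 10), rep(0, 30), rep(12, 10))
  expect_equal(nrow(detectCliffDeletions(d)$deletions), 0)
})

test_that("cliff detection agrees with a brute-force scan on random data", {
  set.seed(202)
  for (k in 1:200) {
    d <- sample(c(0L, 0L, 3L, 15L, 40L), 400, replace = TRUE)
    got <- detectCliffDeletions(d)$deletions
    want <- oracleCliff(d)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("small indel catalogue counts SNPs and InDels up to 20 bp", {
  v <- data.frame(accession_id = c("a", "a", "a", "a", "b"),
                  gene_id = c("g1", "g1", "g1", "g2", "g1"),
                  vtype = c("SNP", "SNP", "SNP", "InDel", "InDel"),
                  indel_len = c(0, 0, 0, 20, 4))
  ct <- catalogueSmallIndels(v)
  expect_equal(ct$per_accession$n_snps, c(3L, 0L))
  expect_equal(ct$per_accession$n_indels, c(1L, 1L))
  g1a <- ct$per_gene[ct$per_gene$accession_id == "a" &
                       ct$per_gene$gene_id == "g1", ]
  expect_equal(c(g1a$n_snps, g1a$n_indels), c(3L, 0L))
  empty <- catalogueSmallIndels(v[0, ])
  expect_equal(nrow(empty$per_accession), 0)
})

test_that("repeat annotation recovers exact, chimeric and absent elements", {
  set.seed(404)
  el <- randomSeq(200)
  lib1 <- Biostrings::DNAStringSet(c(myTE = el))
  # deletion that is an exact copy: one full-length hit, identity 1
  ann <- annotateDeletionRepeats(el, lib1)
  expect_equal(nrow(ann$hits), 1)
  expect_equal(ann$hits$identity, 1)
  expect_equal(c(ann$hits$q_start, ann$hits$q_end), c(1L, 200L))
  expect_false(ann$chimera)
  # nothing matches
  ann0 <- annotateDeletionRepeats(randomSeq(300), lib1)
  expect_equal(nrow(ann0$hits), 0)
  expect_false(ann0$chimera)
  # outer element with a nested inner element: two names, inner nested,
  # chimera flagged
  inner <- randomSeq(150)
  chimera <- paste0(substring(el, 1, 120), inner, substring(el, 121, 200))
  lib2 <- Biostrings::DNAStringSet(c(outer = el, inner = inner))
  ann2 <- annotateDeletionRepeats(chimera, lib2)
  expect_setequal(unique(ann2$hits$name), c("outer", "inner"))
  innerHit <- ann2$hits[ann2$hits$name == "inner", ]
  expect_true(all(innerHit$nested))
  expect_true(ann2$chimera)
  outerSpan <- ann2$spans[ann2$spans$name == "outer", ]
  expect_equal(c(outerSpan$span_start, outerSpan$span_end),
               c(1L, nchar(chimera)))
})

test_that("the planted chimera annotates as outer plus nested MITE", {
  p <- smallPanel()
  te <- simTruth(p$sim)$te
  chroms <- as.character(simGenome(p$sim))
  delSeq <- substring(chroms[[te$chrom]], te$start, te$end)
  ann <- annotateDeletionRepeats(delSeq, simRepeats(p$sim))
  expect_true(ann$chimera)
  innerHits <- ann$hits[ann$hits$name == te$inner_name, ]
  expect_true(all(innerHits$nested))
  expect_equal(min(innerHits$q_start), te$inner_start - te$start + 1L)
})

test_that("hairpin finder recovers a constructed stem-loop", {
  set.seed(505)
  stem <- randomSeq(25)
  s <- paste0(stem, randomSeq(100), oracleRevcomp(stem))
  hp <- findHairpin(s)
  expect_false(is.null(hp))
  expect_gte(hp$stem_len, 25)
  expect_gte(hp$identity, 0.8)
  expect_equal(hp$arm1[1], 1)
  # a stem at identity 0.76 fails the 0.8 threshold
  bad <- strsplit(stem, "")[[1]]
  bad[c(2, 6, 10, 14, 18, 22)] <- vapply(
    bad[c(2, 6, 10, 14, 18, 22)],
    function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  s2 <- paste0(paste(bad, collapse = ""), randomSeq(100),
               oracleRevcomp(stem))
  hp2 <- findHairpin(s2, min_stem = 25, min_stem_identity = 0.8)
  if (!is.null(hp2)) expect_gte(hp2$identity, 0.8)
  # sequences shorter than two stems never fold
  expect_null(findHairpin(randomSeq(30)))
})

test_that("hairpin finder agrees with the exhaustive all-pairs oracle", {
  set.seed(606)
  for (k in 1:6) {
    n <- sample(60:110, 1)
    s <- if (k <= 3) randomSeq(n) else {
      stem <- randomSeq(sample(12:20, 1))
      paste0(randomSeq(10), stem, randomSeq(sample(5:30, 1)),
             oracleRevcomp(stem), randomSeq(10))
    }
    got <- findHairpin(s, min_stem = 10, max_loop = 60,
                       min_stem_identity = 0.8)
    want <- oracleHairpin(s, min_stem = 10, max_loop = 60,
                          min_identity = 0.8)
    if (is.null(want)) {
      expect_null(got, label = s)
    } else {
      expect_equal(got$score, want$score, label = s)
      expect_equal(got$arm1, want$arm1, label = s)
      expect_equal(got$stem_len, want$stem_len, label = s)
    }
  }
})

test_that("random sequences contain no hairpin at the defaults", {
  set.seed(707)
  s <- randomSeq(200)
  expect_null(findHairpin(s))
  expect_null(oracleHairpin(s))
})

test_that("genome hit count finds planted copies on both strands", {
  set.seed(808)
  el <- randomSeq(150)
  chr1 <- paste0(randomSeq(200), el, randomSeq(200))
  chr2 <- paste0(randomSeq(100), oracleRevcomp(el), randomSeq(150), el,
                 randomSeq(100))
  genome <- Biostrings::DNAStringSet(c(c1 = chr1, c2 = chr2))
  expect_equal(genomeHitCount(el, genome), 3L)
  expect_equal(genomeHitCount(randomSeq(150), genome), 0L)
  # a whole chromosome matches itself at least once
  expect_gte(genomeHitCount(chr1, genome), 1L)
})

test_that("the planted MITE occurs at its three genomic loci", {
  p <- smallPanel()
  inner <- as.character(simRepeats(p$sim)[["MITE_inner_Jorge_like"]])
  expect_equal(genomeHitCount(inner, simGenome(p$sim)), 3L)
})
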