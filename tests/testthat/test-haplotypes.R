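# Haplotype signatures, grouping, gene status, arm clusters and cross-ploidy
# sharing.

mkVariant <- function(pos, ref = "A", alt = "T", af = 1, depth = 40,
                      qual = 60, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                            "SNP", "InDel"),
             indel_len = abs(nchar(ref) - nchar(alt)),
             af = af, qual = qual, depth = depth)
}

test_that("homozygous filter keeps af/depth/quality-passing small variants", {
  v <- rbind(mkVariant(10),                       # kept
             mkVariant(20, af = 0.5),             # heterozygous
             mkVariant(30, depth = 9),            # shallow
             mkVariant(40, qual = 29),            # low quality
             mkVariant(50, ref = strrep("A", 26), alt = "A"),  # 25 bp InDel
             mkVariant(60, ref = strrep("A", 21), alt = "A"))  # 20 bp InDel
  kept <- homozygousFilter(v)
  expect_equal(kept$pos, c(10, 60))
})

test_that("signatures are position-sorted and window-restricted", {
  tg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2699),
                               strand = "+", gene_id = "g1")
  v <- rbind(mkVariant(2558, "G", "A"), mkVariant(1101, "C", "T"),
             mkVariant(5000))  # outside the window
  s <- buildSignature(v, tg, captured_fraction = 1)
  expect_equal(s$signature, "1101:C>T;2558:G>A")
  expect_equal(s$n_snps, 2)
  expect_true(s$complete)
  # no variants, full capture: the reference-identical candidate
  s0 <- buildSignature(v[0, ], tg, captured_fraction = 1)
  expect_equal(s0$signature, "")
  # sparse capture flags the signature incomplete
  s2 <- buildSignature(v, tg, captured_fraction = 0.2)
  expect_false(s2$complete)
})

test_that("grouping merges identical signatures with the >=2-members rule", {
  sig <- data.frame(
    accession_id = c("a1", "a2", "a3", "a4", "a5"),
    signature = c("", "", "100:A>T", "100:A>T", "100:A>T;200:G>C"),
    complete = TRUE)
  g <- groupHaplotypes(sig, subgenome = "B", gene_id = "gX")
  expect_equal(nrow(g), 3)
  expect_equal(g$label, c("B1", "B2", "B3"))
  expect_true(g$ref_identical[1])
  expect_equal(g$n_members, c(2L, 2L, 1L))
  expect_equal(g$class, c("shared", "shared", "unique"))
  expect_equal(g$members[2], "a3,a4")
  expect_equal(g$n_snps[3], 2L)
  # all identical to the reference: a single shared group
  allRef <- data.frame(accession_id = paste0("a", 1:6), signature = "",
                       complete = TRUE)
  g1 <- groupHaplotypes(allRef, gene_id = "gY")
  expect_equal(nrow(g1), 1)
  expect_equal(g1$class, "shared")
  expect_true(g1$ref_identical)
})

test_that("grouping is invariant to accession input order", {
  set.seed(9)
  sigs <- c("", "10:A>T", "10:A>T;20:C>G", "30:G>A")
  sig <- data.frame(accession_id = paste0("a", 1:12),
                    signature = sample(sigs, 12, replace = TRUE),
                    complete = TRUE)
  g1 <- groupHaplotypes(sig, gene_id = "g")
  g2 <- groupHaplotypes(sig[sample.int(12), ], gene_id = "g")
  expect_equal(g1, g2)
})

test_that("groups partition the complete signatures", {
  p <- smallPanel()
  groups <- p$report$groups
  sig <- p$report$signatures
  hex <- hexaploidIds(p)
  for (gid in unique(groups$gene_id)) {
    g <- groups[groups$gene_id == gid, ]
    members <- unlist(strsplit(g$members, ","))
    expect_false(any(duplicated(members)))
    complete <- sig[sig$gene_id == gid & sig$complete &
                      sig$accession_id %in% hex, ]
    expect_setequal(members, complete$accession_id)
    expect_equal(sum(g$n_members), nrow(complete))
  }
})

test_that("gene status distinguishes missing from promoter-absent", {
  expect_equal(callGeneStatus(0, 0), "missing_gene")
  expect_equal(callGeneStatus(0, 400), "promoter_absent_cds_present")
  expect_equal(callGeneStatus(1700, 600), "captured")
  expect_equal(callGeneStatus(50, 50), "missing_gene")
})

test_that("nullisomic arm flags need a fully missing arm and a sister arm", {
  dummyTargets <- function(arms, chrom = "chr1B") {
    n <- length(arms)
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(seq(1, by = 3000, length.out = n),
                              width = 1700),
      strand = "+", gene_id = paste0("g", seq_len(n)), trait_tag = "T1-1",
      homoeo_group_id = paste0("H", seq_len(n)), subgenome = "B",
      atg_pos = 1L, arm = arms)
    new("TargetSet", targets = gr,
        partitions = GenomicRanges::GRangesList())
  }
  ts <- dummyTargets(rep(c("1BS", "1BL"), each = 10))
  st <- data.frame(accession_id = "acc", gene_id = paste0("g", 1:20),
                   status = c(rep("missing_gene", 10),
                              rep("captured", 10)))
  fl <- detectMissingArmClusters(st, ts)
  expect_equal(fl$arm, "1BS")
  expect_equal(fl$n_missing, 10L)
  # one captured gene on the arm blocks the flag
  st$status[1] <- "captured"
  expect_equal(nrow(detectMissingArmClusters(st, ts)), 0)
  # an arm with only 2 targets is never flagged at the default threshold
  ts2 <- dummyTargets(c("1BS", "1BS", rep("1BL", 5)))
  st2 <- data.frame(accession_id = "acc", gene_id = paste0("g", 1:7),
                    status = c("missing_gene", "missing_gene",
                               rep("captured", 5)))
  expect_equal(nrow(detectMissingArmClusters(st2, ts2)), 0)
})

test_that("cross-ploidy sharing reports exactly the identical signatures", {
  hx <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 4),
    accession_id = rep(c("H1", "H2", "H3", "H4"), 2),
    signature = c("5:A>T", "5:A>T;9:C>G", "5:A>T", "",
                  "", "", "7:G>A", ""),
    complete = TRUE)
  rel <- data.frame(gene_id = c("g1", "g2", "g2"),
                    accession_id = c("M1", "M1", "E1"),
                    signature = c("5:A>T", "", "11:T>C"),
                    complete = TRUE)
  sh <- crossPloidySharing(hx, rel)
  expect_equal(sort(sh$candidates$recipient), c("H1", "H3"))
  expect_equal(unique(sh$candidates$gene_id), "g1")
  # empty relative signature (g2, M1) is uninformative; E1's unmatched
  # signature is absent from the table
  expect_false("E1" %in% sh$candidates$relative)
  expect_equal(unname(sh$percent_by_relative[["M1"]]), 50)
  expect_equal(unname(sh$percent_by_relative[["E1"]]), 0)
})

test_that("haplotype summary counts unique haplotypes per accession", {
  g <- data.frame(
    gene_id = rep(c("g1", "g2"), c(2, 1)),
    label = c("A1", "A2", "B1"),
    signature = c("", "4:A>T", ""),
    n_members = c(2L, 1L, 3L),
    members = c("x,y", "z", "x,y,z"),
    n_comparison = c(2L, 1L, 3L),
    n_snps = c(0L, 1L, 0L), n_indels = 0L,
    class = c("shared", "unique", "shared"),
    ref_identical = c(TRUE, FALSE, TRUE))
  s <- summarizeHaplotypes(g, n_genes = 2)
  expect_equal(s$per_gene$n_unique, c(1L, 0L))
  expect_equal(s$per_accession_unique$accession_id, "z")
  expect_equal(s$per_accession_unique$percent_of_genes, 50)
  expect_equal(s$percent_reference_identical_only, 50)
  expect_equal(unname(s$snp_histogram[["1"]]), 0.5)
})
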