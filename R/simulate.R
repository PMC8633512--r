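## Synthetic allopolyploid capture panel: a toy hexaploid reference with
## homoeologous gene triads, a mixed-ploidy accession panel with planted
## haplotype / introgression / deletion truth, and a capture simulator that
## emits per-accession VCF and bedGraph files.

#' Configuration for the synthetic panel simulator
#'
#' Returns the full simulation configuration with defaults representing a
#' desk-scale version of a wheat promoter capture experiment: a hexaploid
#' reference of homoeologous triads with 1700 bp promoter+5'UTR targets
#' upstream of each ATG, ~8% substitution divergence between subgenome
#' copies, a mixed-ploidy panel, geometric(0.5) numbers of SNPs per planted
#' haplotype, a 512 bp chimeric transposable element (a MITE with 25 bp
#' terminal inverted repeats nested inside a larger element) whose excision
#' produces cliff-edge coverage gaps, sheared fragments of 400-600 bp and
#' capture by 120-nt probes tiled every 60 nt.
#'
#' @param seed Integer RNG seed; all outputs are byte-identical under the
#'   same seed and configuration.
#' @param n_homoeo_groups Number of homoeologous gene groups (triads).
#' @param subgenomes Subgenome labels (one pseudo-chromosome each).
#' @param homoeologue_divergence Per-base substitution fraction applied
#'   independently to the non-first subgenome copies.
#' @param target_span Target length upstream of the ATG (promoter + 5'UTR).
#' @param n_commercial,n_landrace,n_diploid,n_tetraploid Panel composition in
#'   addition to the single reference accession. The first diploid relative
#'   carries an A-related genome (the introgression donor), the second a
#'   D-related genome.
#' @param haplotype_snp_geometric_p Geometric parameter for SNPs-per-haplotype
#'   (truncated to 1..25).
#' @param shared_haplotypes_range Range of shared haplotypes drawn per target.
#' @param p_reference_only Probability a target has no variation at all among
#'   hexaploids (all identical to the reference).
#' @param p_unique Per-accession probability of drawing a private signature.
#' @param p_indel Probability a signature variant is a small deletion
#'   (1-12 bp) rather than a SNP.
#' @param relative_snp_range Variants per target signature for diploid
#'   relatives.
#' @param mite_spec Terminal-inverted-repeat (stem) and loop length of the
#'   nested MITE.
#' @param te_outer_len,te_insert_at Length of the outer element and the offset
#'   after which the MITE is inserted (chimera length =
#'   `te_outer_len + 2*stem + loop`).
#' @param capture Capture model: fragment length range, minimum
#'   probe-fragment overlap, maximum probe-site mismatch fraction (tau)
#'   and mean fragments per target; variants are only emitted where depth >=
#'   `min_emit_depth`.
#' @param screen Specificity-screen thresholds used when designing baits on
#'   the synthetic genome (stringency must exceed homoeologue identity).
#' @return A named list of class `promcap_sim_config`.
#' @export
panelSimConfig <- function(seed = 1,
                           n_homoeo_groups = 30,
                           subgenomes = c("A", "B", "D"),
                           homoeologue_divergence = 0.08,
                           target_span = 1700,
                           n_commercial = 10, n_landrace = 4,
                           n_diploid = 2, n_tetraploid = 1,
                           haplotype_snp_geometric_p = 0.5,
                           shared_haplotypes_range = c(1, 4),
                           p_reference_only = 0.25,
                           p_unique = 0.08,
                           p_indel = 0.15,
                           relative_snp_range = c(8, 18),
                           mite_spec = list(stem = 25, loop = 178),
                           te_outer_len = 284, te_insert_at = 190,
                           capture = list(fragment_len_range = c(400, 600),
                                          min_overlap = 50,
                                          max_mismatch_fraction = 0.10,
                                          mean_fragments_per_target = 200,
                                          min_emit_depth = 10, qual = 60),
                           screen = list(seed_len = 16, min_identity = 0.96,
                                         min_aln_len = 100)) {
  cfg <- list(seed = as.integer(seed), n_homoeo_groups = n_homoeo_groups,
              subgenomes = subgenomes,
              homoeologue_divergence = homoeologue_divergence,
              target_span = target_span,
              utr_len = 235, exon1_len = 300, intron_len = 120,
              exon2_len = 180, flank_left = 500, flank_right = 300,
              n_commercial = n_commercial, n_landrace = n_landrace,
              n_diploid = n_diploid, n_tetraploid = n_tetraploid,
              haplotype_snp_geometric_p = haplotype_snp_geometric_p,
              shared_haplotypes_range = shared_haplotypes_range,
              p_reference_only = p_reference_only, p_unique = p_unique,
              p_indel = p_indel, relative_snp_range = relative_snp_range,
              mite_spec = mite_spec, te_outer_len = te_outer_len,
              te_insert_at = te_insert_at,
              capture = capture, screen = screen)
  stopifnot(homoeologue_divergence >= 0, homoeologue_divergence <= 1,
            capture$max_mismatch_fraction >= 0,
            capture$max_mismatch_fraction <= 1)
  cfg$unit_len <- cfg$flank_left + cfg$target_span + cfg$exon1_len +
    cfg$intron_len + cfg$exon2_len + cfg$flank_right
  class(cfg) <- c("promcap_sim_config", "list")
  cfg
}

.chromName <- function(sg) paste0("chr1", sg)
.chromSub <- function(chrom) substring(chrom, nchar(chrom))
.LABEL_TO_SUB <- c(A = "A", B = "B", D = "D", Am = "A", S = "B", U = "D")

## Per-unit (gene) coordinate layout, 1-based offsets within the unit.
.unitLayout <- function(cfg) {
  fl <- cfg$flank_left
  list(target = c(fl + 1L, fl + cfg$target_span),
       promoter = c(fl + 1L, fl + cfg$target_span - cfg$utr_len),
       five_utr = c(fl + cfg$target_span - cfg$utr_len + 1L,
                    fl + cfg$target_span),
       atg = fl + cfg$target_span + 1L,
       exon1 = c(fl + cfg$target_span + 1L,
                 fl + cfg$target_span + cfg$exon1_len),
       intron = c(fl + cfg$target_span + cfg$exon1_len + 1L,
                  fl + cfg$target_span + cfg$exon1_len + cfg$intron_len),
       exon2 = c(fl + cfg$target_span + cfg$exon1_len + cfg$intron_len + 1L,
                 fl + cfg$target_span + cfg$exon1_len + cfg$intron_len +
                   cfg$exon2_len))
}

#' Build the synthetic allopolyploid reference
#'
#' Generates one pseudo-chromosome per subgenome, each carrying one copy of
#' every homoeologous gene group at identical layout offsets; non-first
#' subgenome copies are independently mutated at the configured divergence.
#' One promoter (group 5, subgenome B by default) carries a planted chimeric
#' transposable element: a MITE with perfect terminal inverted repeats nested
#' inside a larger element, mirroring a nested Jorge-inside-Coeus insertion;
#' the repeat library contains both elements separately and the MITE is also
#' planted at two additional intergenic loci.
#'
#' @param config A [panelSimConfig()] list.
#' @return A list with `genome` (DNAStringSet), `targets` ([TargetSet-class]),
#'   `repeats` (DNAStringSet), `annotation` (GRanges ready for GFF3 export)
#'   and `te` (placement bookkeeping used by the truth tables).
#' @export
buildReferenceGenome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  lay <- .unitLayout(cfg)
  G <- cfg$n_homoeo_groups
  U <- cfg$unit_len
  L <- G * U
  sgs <- cfg$subgenomes

  ancestral <- .charVec(.randomDna(L))
  chroms <- list()
  for (i in seq_along(sgs)) {
    cc <- ancestral
    if (i > 1) cc <- .mutateChars(cc, cfg$homoeologue_divergence)
    chroms[[.chromName(sgs[i])]] <- cc
  }

  ## chimeric TE: inner MITE with perfect terminal inverted repeats
  stem <- cfg$mite_spec$stem
  loop <- cfg$mite_spec$loop
  stemSeq <- .randomDna(stem)
  innerSeq <- paste0(stemSeq, .randomDna(loop), .revcomp(stemSeq))
  outerSeq <- .randomDna(cfg$te_outer_len)
  ins <- cfg$te_insert_at
  chimera <- paste0(substring(outerSeq, 1, ins), innerSeq,
                    substring(outerSeq, ins + 1, cfg$te_outer_len))
  teLen <- nchar(chimera)

  teGroup <- min(5L, G)
  teChrom <- .chromName(if ("B" %in% sgs) "B" else sgs[length(sgs)])
  teOff <- 600L  # offset of first TE base within the target
  u0 <- (teGroup - 1L) * U
  teStart <- u0 + lay$target[1] - 1L + teOff       # genomic start
  teEnd <- teStart + teLen - 1L
  chroms[[teChrom]][teStart:teEnd] <- .charVec(chimera)
  innerStart <- teStart + ins
  innerEnd <- innerStart + nchar(innerSeq) - 1L

  ## two additional intergenic MITE copies (for genome hit counting)
  extra <- list(list(chrom = .chromName(sgs[1]), group = min(12L, G)),
                list(chrom = .chromName(sgs[length(sgs)]),
                     group = min(20L, G)))
  extraLoci <- do.call(rbind, lapply(extra, function(e) {
    s <- (e$group - 1L) * U + 100L
    chroms[[e$chrom]][s:(s + nchar(innerSeq) - 1L)] <<- .charVec(innerSeq)
    data.frame(name = "MITE_inner_Jorge_like", chrom = e$chrom,
               start = s, end = s + nchar(innerSeq) - 1L)
  }))

  genome <- DNAStringSet(vapply(chroms, paste, character(1), collapse = ""))

  ## target catalogue + annotation
  rows <- list(); ann <- list(); parts <- list()
  for (g in seq_len(G)) {
    u0 <- (g - 1L) * U
    for (sg in sgs) {
      cn <- .chromName(sg)
      gid <- sprintf("TraesSY%s01G%03d", sg, g)
      trait <- sprintf("T%d", ((g - 1L) %% 10L) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, trait_tag = sprintf("%s-%d", trait, g),
        homoeo_group_id = sprintf("HG%03d", g), subgenome = sg,
        chrom = cn, strand = "+", atg_pos = u0 + lay$atg,
        span = cfg$target_span,
        arm = paste0("1", sg, if (g <= G / 2) "S" else "L"))
      gene <- GRanges(cn, IRanges(u0 + lay$five_utr[1], u0 + lay$exon2[2]),
                      strand = "+", type = "gene", ID = gid,
                      Parent = NA_character_)
      utr <- GRanges(cn, IRanges(u0 + lay$five_utr[1], u0 + lay$five_utr[2]),
                     strand = "+", type = "five_prime_UTR",
                     ID = paste0(gid, ".utr"), Parent = gid)
      ex1 <- GRanges(cn, IRanges(u0 + lay$exon1[1], u0 + lay$exon1[2]),
                     strand = "+", type = "exon",
                     ID = paste0(gid, ".e1"), Parent = gid)
      ex2 <- GRanges(cn, IRanges(u0 + lay$exon2[1], u0 + lay$exon2[2]),
                     strand = "+", type = "exon",
                     ID = paste0(gid, ".e2"), Parent = gid)
      ann[[length(ann) + 1L]] <- c(gene, utr, ex1, ex2)
      pr <- GRanges(cn,
                    IRanges(c(u0 + lay$promoter[1], u0 + lay$five_utr[1],
                              u0 + lay$exon1[1], u0 + lay$exon2[1],
                              u0 + lay$intron[1]),
                            c(u0 + lay$promoter[2], u0 + lay$five_utr[2],
                              u0 + lay$exon1[2], u0 + lay$exon2[2],
                              u0 + lay$intron[2])),
                    part = c("promoter", "five_utr", "exon", "exon",
                             "intron"))
      parts[[gid]] <- sort(pr)
    }
  }
  tdf <- do.call(rbind, rows)
  tgr <- GRanges(tdf$chrom,
                 IRanges(tdf$atg_pos - tdf$span, tdf$atg_pos - 1L),
                 strand = tdf$strand, gene_id = tdf$gene_id,
                 trait_tag = tdf$trait_tag,
                 homoeo_group_id = tdf$homoeo_group_id,
                 subgenome = tdf$subgenome,
                 atg_pos = as.integer(tdf$atg_pos), arm = tdf$arm)
  ord <- order(as.character(seqnames(tgr)), start(tgr))
  targets <- new("TargetSet", targets = tgr[ord],
                 partitions = GRangesList(parts)[tgr$gene_id[ord]])

  ## homoeologous promoters must actually differ, otherwise the specificity
  ## screen has nothing to distinguish
  for (g in seq_len(G)) {
    u0 <- (g - 1L) * U
    idx <- (u0 + lay$target[1]):(u0 + lay$target[2])
    seqs <- vapply(chroms, function(cc) paste(cc[idx], collapse = ""),
                   character(1))
    if (anyDuplicated(seqs)) {
      stop("homoeologue divergence too low: identical promoter copies in ",
           sprintf("group %d", g))
    }
  }

  repeats <- DNAStringSet(c(DTH_syn_Coeus_like = outerSeq,
                            MITE_inner_Jorge_like = innerSeq))

  teGene <- sprintf("TraesSY%s01G%03d", .chromSub(teChrom), teGroup)
  te <- list(outer_name = "DTH_syn_Coeus_like",
             inner_name = "MITE_inner_Jorge_like",
             gene_id = teGene, chrom = teChrom,
             start = teStart, end = teEnd,
             inner_start = innerStart, inner_end = innerEnd,
             target_offset = teOff,
             extra_loci = extraLoci)

  list(genome = genome, targets = targets, repeats = repeats,
       annotation = unlist(GRangesList(ann)), te = te, config = cfg)
}

## ---- variant machinery ------------------------------------------------------

## Draw the number of variants for one haplotype: geometric(p) truncated to
## 1..kmax.
.rTruncGeom <- function(p, kmax = 25L) {
  probs <- p * (1 - p)^(0:(kmax - 1L))
  sample.int(kmax, 1L, prob = probs)
}

## Build one signature: variant table in VCF representation on `chrom` chars.
## Offsets are positions within the target (1-based); `grid` is the pool of
## allowed offsets (spaced so capture is never locally saturated).
.drawSignature <- function(n, grid, tStart, cc, p_indel) {
  offs <- sort(grid[sample.int(length(grid), n)])
  recs <- lapply(offs, function(off) {
    pos <- tStart + off - 1L
    if (runif(1) < p_indel) {
      len <- sample.int(12L, 1L)
      data.frame(pos = pos - 1L,
                 ref = paste(cc[(pos - 1L):(pos + len - 1L)], collapse = ""),
                 alt = cc[pos - 1L], kind = "del",
                 del_start = pos, del_end = pos + len - 1L)
    } else {
      data.frame(pos = pos, ref = cc[pos],
                 alt = .substituteBase(cc[pos]), kind = "snp",
                 del_start = NA_integer_, del_end = NA_integer_)
    }
  })
  do.call(rbind, recs)
}

.signatureKey <- function(sig) {
  if (is.null(sig) || !nrow(sig)) return("")
  paste(sprintf("%d:%s>%s", sig$pos, sig$ref, sig$alt), collapse = ";")
}

#' Simulate the accession panel with planted truth
#'
#' Plants, for every target, a set of shared haplotypes (variant counts
#' following a truncated geometric distribution, related haplotypes sharing a
#' core signature plus/minus one or two variants) and occasional private
#' signatures; copies the diploid donor's exact signature into the configured
#' introgression recipients; removes the planted transposable element from
#' the deletion carriers (and only the nested MITE from one carrier);
#' deletes one whole chromosome arm's targets from the nullisomic accession;
#' and records every planted fact in the truth tables.
#'
#' @param ref Result of [buildReferenceGenome()].
#' @param config A [panelSimConfig()] list (defaults to the one used to build
#'   the reference).
#' @return A [WheatPanelSim-class].
#' @export
simulatePanel <- function(ref, config = ref$config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  lay <- .unitLayout(cfg)
  G <- cfg$n_homoeo_groups
  U <- cfg$unit_len
  chromChars <- lapply(as.character(ref$genome), .charVec)
  tg <- targetRanges(ref$targets)

  ## ---- panel ----------------------------------------------------------------
  hexComp <- "A,A,B,B,D,D"
  commCodes <- c("AB", "AV", "BW", "CD", "EL", "FR", "GT", "HM", "IQ", "JB",
                 "KA", "LM", "MN", "NO", "OP", "PQ")
  acc <- rbind(
    data.frame(accession_id = "CS_REF", display_code = "CS",
               category = "reference", composition = hexComp),
    if (cfg$n_commercial > 0) data.frame(
      accession_id = sprintf("CV%02d", seq_len(cfg$n_commercial)),
      display_code = commCodes[seq_len(cfg$n_commercial)],
      category = "commercial", composition = hexComp),
    if (cfg$n_landrace > 0) data.frame(
      accession_id = sprintf("WL%02d", seq_len(cfg$n_landrace)),
      display_code = sprintf("W%03d", 100L + seq_len(cfg$n_landrace)),
      category = "landrace", composition = hexComp),
    if (cfg$n_diploid > 0) data.frame(
      accession_id = sprintf("DR%s1", c("A", "D")[seq_len(cfg$n_diploid)]),
      display_code = sprintf("M%03d", 30L + seq_len(cfg$n_diploid)),
      category = "diploid_relative",
      composition = c("Am,Am", "D,D")[seq_len(cfg$n_diploid)]),
    if (cfg$n_tetraploid > 0) data.frame(
      accession_id = sprintf("TK%d", seq_len(cfg$n_tetraploid)),
      display_code = sprintf("KR%d", seq_len(cfg$n_tetraploid)),
      category = "tetraploid", composition = "A,A,B,B"))
  hexIds <- acc$accession_id[acc$category %in%
                               c("reference", "commercial", "landrace")]

  ## ---- structural specs -----------------------------------------------------
  te <- ref$te
  nHex <- length(hexIds)
  nonRef <- setdiff(hexIds, "CS_REF")
  delCarriers <- nonRef[seq_len(min(5L, length(nonRef)))]
  innerCarrier <- if (cfg$n_landrace >= 4) "WL04" else tail(nonRef, 1)
  delCarriers <- setdiff(delCarriers, innerCarrier)
  nullAcc <- if (cfg$n_commercial >= 9) "CV09" else NA_character_
  nullChrom <- .chromName("B")
  nullArm <- "1BS"
  missAcc <- if (cfg$n_landrace >= 2) "WL02" else NA_character_
  missGene <- sprintf("TraesSYD01G%03d", min(8L, G))
  promAbsAcc <- if (cfg$n_commercial >= 6) "CV06" else NA_character_
  promAbsGene <- sprintf("TraesSYA01G%03d", min(11L, G))

  introTargets <- sprintf("TraesSYA01G%03d",
                          intersect(c(3L, 17L, 24L), seq_len(G)))
  introDonor <- if (cfg$n_diploid >= 1) "DRA1" else NA_character_
  introRecipients <- if (cfg$n_commercial >= 7) c("CV03", "CV07")
                     else character(0)

  ## per-accession edits: list(acc -> list(chrom -> list(snps=df, dels=df,
  ## vcf=df)))
  edits <- setNames(lapply(acc$accession_id, function(a)
    setNames(lapply(names(ref$genome), function(cn)
      list(snps = data.frame(pos = integer(0), alt = character(0)),
           dels = data.frame(start = integer(0), end = integer(0)),
           vcf = data.frame(pos = integer(0), ref = character(0),
                            alt = character(0), kind = character(0),
                            check_pos = integer(0)))),
      names(ref$genome))), acc$accession_id)

  addSignature <- function(a, cn, sig) {
    if (is.null(sig) || !nrow(sig)) return()
    e <- edits[[a]][[cn]]
    sn <- sig[sig$kind == "snp", , drop = FALSE]
    dl <- sig[sig$kind == "del", , drop = FALSE]
    e$snps <- rbind(e$snps, data.frame(pos = sn$pos, alt = sn$alt))
    if (nrow(dl)) {
      e$dels <- rbind(e$dels,
                      data.frame(start = dl$del_start, end = dl$del_end))
    }
    e$vcf <- rbind(e$vcf, data.frame(
      pos = sig$pos, ref = sig$ref, alt = sig$alt, kind = sig$kind,
      check_pos = ifelse(sig$kind == "del", sig$pos, sig$pos)))
    edits[[a]][[cn]] <<- e
  }
  addDeletion <- function(a, cn, s, e2) {
    edits[[a]][[cn]]$dels <<-
      rbind(edits[[a]][[cn]]$dels, data.frame(start = s, end = e2))
  }

  ## apply structural deletions first so haplotype planting can skip the
  ## affected (accession, gene) pairs
  tgDf <- as.data.frame(mcols(tg))
  tgDf$chrom <- as.character(seqnames(tg))
  tgDf$t_start <- start(tg); tgDf$t_end <- end(tg)
  rownames(tgDf) <- tgDf$gene_id
  geneWindow <- function(gid) {
    g0 <- tgDf[gid, "t_start"] - lay$target[1] + 1L  # unit start
    c(g0, g0 + U - 1L)
  }
  missingRows <- list(); deletionRows <- list()
  skipPairs <- character(0)  # "acc|gene" with no usable capture

  for (a in delCarriers) {
    addDeletion(a, te$chrom, te$start, te$end)
    deletionRows[[length(deletionRows) + 1L]] <- data.frame(
      event = "del1_chimera", gene_id = te$gene_id, accession_id = a,
      chrom = te$chrom, start = te$start, end = te$end,
      elements = paste(te$outer_name, te$inner_name, sep = "+"))
  }
  if (!is.na(innerCarrier)) {
    addDeletion(innerCarrier, te$chrom, te$inner_start, te$inner_end)
    deletionRows[[length(deletionRows) + 1L]] <- data.frame(
      event = "del3_inner", gene_id = te$gene_id,
      accession_id = innerCarrier, chrom = te$chrom,
      start = te$inner_start, end = te$inner_end,
      elements = te$inner_name)
  }
  if (!is.na(missAcc)) {
    gw <- geneWindow(missGene)
    addDeletion(missAcc, tgDf[missGene, "chrom"],
                tgDf[missGene, "t_start"],
                gw[1] + lay$exon2[2] - 1L)
    missingRows[[length(missingRows) + 1L]] <- data.frame(
      accession_id = missAcc, gene_id = missGene, type = "missing_gene",
      arm = tgDf[missGene, "arm"])
    skipPairs <- c(skipPairs, paste(missAcc, missGene, sep = "|"))
  }
  if (!is.na(promAbsAcc)) {
    ## remove the promoter but keep its last 85 bp (and the 5'UTR), so the
    ## gene profiles as promoter-absent-CDS-present rather than missing
    addDeletion(promAbsAcc, tgDf[promAbsGene, "chrom"],
                tgDf[promAbsGene, "t_start"],
                tgDf[promAbsGene, "t_start"] + cfg$target_span -
                  cfg$utr_len - 86L)
    missingRows[[length(missingRows) + 1L]] <- data.frame(
      accession_id = promAbsAcc, gene_id = promAbsGene,
      type = "promoter_absent_cds_present",
      arm = tgDf[promAbsGene, "arm"])
    skipPairs <- c(skipPairs, paste(promAbsAcc, promAbsGene, sep = "|"))
  }
  if (!is.na(nullAcc)) {
    armGenes <- tgDf$gene_id[tgDf$arm == nullArm]
    for (gid in armGenes) {
      gw <- geneWindow(gid)
      addDeletion(nullAcc, tgDf[gid, "chrom"], gw[1], gw[2])
      missingRows[[length(missingRows) + 1L]] <- data.frame(
        accession_id = nullAcc, gene_id = gid, type = "nullisomic_arm",
        arm = nullArm)
      skipPairs <- c(skipPairs, paste(nullAcc, gid, sep = "|"))
    }
  }

  ## ---- haplotype planting ---------------------------------------------------
  ## allowed variant offsets within the target: spaced 50 bp so that no
  ## probe-fragment overlap ever accumulates a mismatch fraction above the
  ## capture threshold purely from planted variation
  gridFor <- function(gid) {
    grid <- seq(130L, cfg$target_span - 130L, by = 50L)
    if (gid == te$gene_id) {
      lo <- te$target_offset - 30L
      hi <- te$target_offset + (te$end - te$start) + 30L
      grid <- grid[grid < lo | grid > hi]
    }
    grid
  }

  hapRows <- list(); relRows <- list(); introRows <- list()
  p <- cfg$haplotype_snp_geometric_p
  sampleRange <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L

  for (i in seq_len(nrow(tgDf))) {
    gid <- tgDf$gene_id[i]; cn <- tgDf$chrom[i]
    tStart <- tgDf$t_start[i]
    cc <- chromChars[[cn]]
    grid <- gridFor(gid)
    used <- c("")
    drawDistinct <- function(n) {
      for (k in 1:50) {
        sig <- .drawSignature(n, grid, tStart, cc, cfg$p_indel)
        key <- .signatureKey(sig)
        if (!key %in% used) {
          used <<- c(used, key)
          return(sig)
        }
      }
      stop("could not draw a distinct signature")
    }
    deriveRelated <- function(base) {
      ## shared core plus/minus 1-2 variants
      for (k in 1:50) {
        sig <- base
        if (nrow(sig) > 2 && runif(1) < 0.5) {
          sig <- sig[-sample.int(nrow(sig), sample(1:2, 1)), , drop = FALSE]
        } else {
          addn <- sample(1:2, 1)
          ## exclude every offset occupied by an existing variant,
          ## including the bases a small deletion removes
          occupied <- unlist(lapply(seq_len(nrow(sig)), function(r) {
            if (sig$kind[r] == "del") {
              (sig$pos[r]):(sig$del_end[r]) - tStart + 1L
            } else {
              sig$pos[r] - tStart + 1L
            }
          }))
          pool <- setdiff(grid, occupied)
          if (length(pool) >= addn) {
            sig <- rbind(sig, .drawSignature(addn, pool, tStart, cc,
                                             cfg$p_indel))
            sig <- sig[order(sig$pos), , drop = FALSE]
          }
        }
        key <- .signatureKey(sig)
        if (nrow(sig) && nrow(sig) <= 25 && !key %in% used) {
          used <<- c(used, key)
          return(sig)
        }
      }
      drawDistinct(.rTruncGeom(p))
    }

    ## shared haplotypes for this target (signature index 0 = reference)
    refOnly <- runif(1) < cfg$p_reference_only
    sigs <- list()
    if (!refOnly) {
      k <- sampleRange(cfg$shared_haplotypes_range)
      for (j in seq_len(k)) {
        sigs[[j]] <- if (j > 1 && runif(1) < 0.5)
          deriveRelated(sigs[[sample.int(j - 1L, 1L)]])
        else drawDistinct(.rTruncGeom(p))
      }
    }

    ## donor signature for introgression targets
    donorSig <- NULL
    if (gid %in% introTargets && !is.na(introDonor)) {
      nd <- sampleRange(cfg$relative_snp_range)
      donorSig <- drawDistinct(nd)
    }

    for (a in hexIds) {
      if (paste(a, gid, sep = "|") %in% skipPairs) next
      sig <- NULL
      if (a == "CS_REF") {
        sig <- NULL  # the reference is identical to itself
      } else if (!is.null(donorSig) && a %in% introRecipients) {
        sig <- donorSig
      } else if (!refOnly) {
        if (runif(1) < cfg$p_unique) {
          sig <- if (runif(1) < 0.5 && length(sigs))
            deriveRelated(sigs[[sample.int(length(sigs), 1L)]])
          else drawDistinct(.rTruncGeom(p))
        } else {
          pick <- sample.int(length(sigs) + 1L, 1L)  # +1 = reference
          if (pick <= length(sigs)) sig <- sigs[[pick]]
        }
      }
      addSignature(a, cn, sig)
      hapRows[[length(hapRows) + 1L]] <- data.frame(
        gene_id = gid, accession_id = a, signature = .signatureKey(sig),
        n_variants = if (is.null(sig)) 0L else nrow(sig))
    }
    if (!is.null(donorSig)) {
      addSignature(introDonor, cn, donorSig)
      relRows[[length(relRows) + 1L]] <- data.frame(
        gene_id = gid, accession_id = introDonor,
        signature = .signatureKey(donorSig))
      for (r in introRecipients) {
        introRows[[length(introRows) + 1L]] <- data.frame(
          donor = introDonor, gene_id = gid, recipient = r)
      }
    }

    ## relatives: own (distinct) signatures on their related subgenome
    sg <- tgDf$subgenome[i]
    for (a in acc$accession_id[acc$category %in%
                                 c("diploid_relative", "tetraploid")]) {
      labs <- strsplit(acc$composition[acc$accession_id == a], ",")[[1]]
      related <- unique(.LABEL_TO_SUB[labs])
      if (!sg %in% related) next
      if (!is.null(donorSig) && a == introDonor) next  # already planted
      nd <- if (acc$category[acc$accession_id == a] == "tetraploid")
        .rTruncGeom(p) else
          sampleRange(cfg$relative_snp_range)
      sig <- drawDistinct(nd)
      addSignature(a, cn, sig)
      relRows[[length(relRows) + 1L]] <- data.frame(
        gene_id = gid, accession_id = a, signature = .signatureKey(sig))
    }
  }

  truth <- list(
    haplotypes = do.call(rbind, hapRows),
    relative_haplotypes = do.call(rbind, relRows),
    introgressions = if (length(introRows)) do.call(rbind, introRows)
                     else data.frame(donor = character(0),
                                     gene_id = character(0),
                                     recipient = character(0)),
    deletions = if (length(deletionRows)) do.call(rbind, deletionRows)
                else data.frame(),
    missing = if (length(missingRows)) do.call(rbind, missingRows)
              else data.frame(accession_id = character(0),
                              gene_id = character(0), type = character(0),
                              arm = character(0)),
    arm_flags = if (!is.na(nullAcc))
      data.frame(accession_id = nullAcc, arm = nullArm)
    else data.frame(accession_id = character(0), arm = character(0)),
    repeat_loci = rbind(
      data.frame(name = te$inner_name, chrom = te$chrom,
                 start = te$inner_start, end = te$inner_end),
      te$extra_loci))

  new("WheatPanelSim", genome = ref$genome, targets = ref$targets,
      repeats = ref$repeats, accessions = acc, edits = edits,
      truth = c(truth, list(te = te, annotation = ref$annotation)),
      config = unclass(cfg))
}

## ---- capture simulation -----------------------------------------------------

#' Simulate hybridization capture for every accession
#'
#' Draws sheared fragments uniformly over each accession's chromosomes
#' (fragment count proportional to chromosome length, modelling equal library
#' mass per accession, so diploids reach roughly three times hexaploid
#' depth). A probe binds a genomic site when its mismatch fraction over the
#' whole 120-nt placement is at most tau (hybridization integrates the full
#' bait length); a fragment is captured when it overlaps a bound site by at
#' least `min_overlap` bases. Probe placements comprise each probe's own
#' locus and the positionally homoeologous locus on every other chromosome
#' the accession carries, so cross-subgenome capture appears exactly when tau
#' reaches the homoeologue divergence. Captured fragments are piled into
#' reference-coordinate depth; bases deleted in an accession receive no
#' coverage (cliff-edge gaps). Homozygous variant records (allele frequency
#' 1.0) are emitted for every planted edit whose site reaches the minimum
#' emission depth.
#'
#' @param sim A [WheatPanelSim-class].
#' @param probeset A [ProbeSet-class] designed on the same genome.
#' @param tau Maximum probe-fragment mismatch fraction over the overlap
#'   (defaults to the config's capture `max_mismatch_fraction`).
#' @return A named list (by accession) with components `vcf` (variant
#'   data.frame), `depth` (named list of per-chromosome integer depth
#'   vectors in reference coordinates), `cross_bases` (captured overlap bases
#'   attributable to probes of a different subgenome than the fragment's
#'   origin chromosome) and `captured_bases` (bases at depth >= 1).
#' @export
simulateCapture <- function(sim, probeset, tau = NULL) {
  cfg <- simConfig(sim)
  cap <- cfg$capture
  if (is.null(tau)) tau <- cap$max_mismatch_fraction
  set.seed(cfg$seed + 2L)
  rp <- retainedProbes(probeset)
  chromChars <- lapply(as.character(simGenome(sim)), .charVec)
  chromLens <- lengths(chromChars)
  acc <- simAccessions(sim)
  fr <- cap$fragment_len_range
  nPerBp <- cap$mean_fragments_per_target * cfg$n_homoeo_groups *
    length(cfg$subgenomes)  # total fragments for a full hexaploid

  probeChars <- NULL
  if (nrow(rp)) {
    probeChars <- do.call(rbind, strsplit(rp$sequence, "", fixed = TRUE))
  }
  probeSub <- .chromSub(rp$chrom)

  out <- list()
  for (ai in seq_len(nrow(acc))) {
    a <- acc$accession_id[ai]
    labs <- strsplit(acc$composition[ai], ",", fixed = TRUE)[[1]]
    chromsA <- unique(.chromName(unname(.LABEL_TO_SUB[labs])))
    chromsA <- chromsA[!is.na(chromsA)]
    totalLen <- sum(chromLens[chromsA])
    depth <- list(); crossBases <- 0
    vcfRows <- list()
    for (cn in names(chromChars)) {
      depth[[cn]] <- integer(chromLens[[cn]])
    }
    for (cn in chromsA) {
      L <- chromLens[[cn]]
      ed <- simEdits(sim)[[a]][[cn]]
      deleted <- logical(L)
      if (nrow(ed$dels)) {
        for (k in seq_len(nrow(ed$dels))) {
          deleted[ed$dels$start[k]:ed$dels$end[k]] <- TRUE
        }
      }
      accChars <- chromChars[[cn]]
      if (nrow(ed$snps)) accChars[ed$snps$pos] <- ed$snps$alt
      mapRef <- which(!deleted)
      accSeq <- accChars[mapRef]
      La <- length(accSeq)
      posToAcc <- cumsum(!deleted)

      ## probe placements on this chromosome (identical layout across
      ## subgenome chromosomes, so the probe's own coordinates transfer)
      if (nrow(rp)) {
        ok <- !deleted[rp$start] & (rp$start + 119L) <= L
        sStart <- posToAcc[rp$start]
        ok <- ok & (sStart + 119L) <= La
        siteIdx <- which(ok)
      } else siteIdx <- integer(0)
      nfrag <- as.integer(round(nPerBp * chromLens[[cn]] / totalLen))
      lens <- fr[1] + sample.int(fr[2] - fr[1] + 1L, nfrag,
                                 replace = TRUE) - 1L
      starts <- 1L + floor(runif(nfrag) * (La - lens))
      fragIR <- IRanges(starts, width = lens)

      capturedFrag <- logical(nfrag)
      if (length(siteIdx)) {
        ss <- sStart[siteIdx]
        idxMat <- outer(ss, 0:119, "+")
        accMat <- matrix(accSeq[idxMat], nrow = length(ss))
        mm <- probeChars[siteIdx, , drop = FALSE] != accMat
        ## a probe binds a site when its mismatch fraction over the whole
        ## 120-nt placement is at most tau (hybridization integrates the
        ## full bait length)
        siteOK <- rowSums(mm) / 120 <= tau
        if (any(siteOK)) {
          ssOK <- ss[siteOK]
          siteIR <- IRanges(ssOK, width = 120L)
          ov <- findOverlaps(fragIR, siteIR)
          if (length(ov)) {
            q <- queryHits(ov); s <- subjectHits(ov)
            os <- pmax(starts[q], ssOK[s])
            oe <- pmin(starts[q] + lens[q] - 1L, ssOK[s] + 119L)
            ol <- oe - os + 1L
            qual <- ol >= cap$min_overlap
            capturedFrag[unique(q[qual])] <- TRUE
            cross <- qual &
              probeSub[siteIdx][siteOK][s] != .chromSub(cn)
            crossBases <- crossBases + sum(ol[cross])
          }
        }
      }
      if (any(capturedFrag)) {
        cov <- as.integer(coverage(fragIR[capturedFrag], width = La))
        depth[[cn]][mapRef] <- cov
      }
      ## variant emission
      if (nrow(ed$vcf)) {
        d <- depth[[cn]][ed$vcf$check_pos]
        keep <- d >= cap$min_emit_depth
        if (any(keep)) {
          vcfRows[[length(vcfRows) + 1L]] <- data.frame(
            chrom = cn, pos = ed$vcf$pos[keep], ref = ed$vcf$ref[keep],
            alt = ed$vcf$alt[keep], af = 1.0, qual = cap$qual,
            depth = d[keep])
        }
      }
    }
    vcf <- if (length(vcfRows)) do.call(rbind, vcfRows) else
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), af = numeric(0),
                 qual = numeric(0), depth = integer(0))
    vcf <- vcf[order(vcf$chrom, vcf$pos), , drop = FALSE]
    out[[a]] <- list(vcf = vcf, depth = depth, cross_bases = crossBases,
                     captured_bases = sum(vapply(depth, function(d)
                       sum(d > 0), numeric(1))))
  }
  out
}

#' Write all panel artifacts to a directory
#'
#' Writes the reference genome (FASTA), annotation (GFF3), target catalogue
#' and accession tables (TSV), repeat library (FASTA), per-accession VCF and
#' bedGraph files, the planted-truth tables (TSV) and a manifest with md5
#' checksums of every file.
#'
#' @param sim A [WheatPanelSim-class].
#' @param capture Result of [simulateCapture()].
#' @param outdir Output directory.
#' @param force Overwrite a non-empty directory (default FALSE).
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
writePanel <- function(sim, capture, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ",
         outdir)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tg <- targetRanges(simTargets(sim))
  tdf <- data.frame(gene_id = tg$gene_id, trait_tag = tg$trait_tag,
                    homoeo_group_id = tg$homoeo_group_id,
                    subgenome = tg$subgenome,
                    chrom = as.character(seqnames(tg)),
                    strand = as.character(strand(tg)),
                    atg_pos = tg$atg_pos, span = width(tg), arm = tg$arm)
  files <- character(0)
  wr <- function(fn) files <<- c(files, file.path(outdir, fn))

  writeXStringSet(simGenome(sim), file.path(outdir, "genome.fa"))
  wr("genome.fa")
  export(simTruth(sim)$annotation, file.path(outdir, "annotation.gff3"),
         format = "gff3")
  wr("annotation.gff3")
  write.table(tdf, file.path(outdir, "targets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wr("targets.tsv")
  writeXStringSet(simRepeats(sim), file.path(outdir, "repeats.fa"))
  wr("repeats.fa")
  write.table(simAccessions(sim), file.path(outdir, "accessions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wr("accessions.tsv")

  for (a in names(capture)) {
    vp <- file.path(outdir, paste0(a, ".vcf"))
    writeVcfVariants(capture[[a]]$vcf, vp, sample_id = a)
    wr(basename(vp))
    bp <- file.path(outdir, paste0(a, ".bedGraph"))
    writeBedGraph(capture[[a]]$depth, bp)
    wr(basename(bp))
  }

  tr <- simTruth(sim)
  for (nm in c("haplotypes", "relative_haplotypes", "introgressions",
               "deletions", "missing", "arm_flags", "repeat_loci")) {
    fn <- paste0("truth_", nm, ".tsv")
    write.table(tr[[nm]], file.path(outdir, fn), sep = "\t",
                quote = FALSE, row.names = FALSE)
    wr(fn)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(md5sum(files)))
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
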