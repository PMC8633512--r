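## Pipeline orchestration and headline reporting: runs profiling ->
## haplotypes -> structural variants -> TFBS over a directory of panel
## artifacts and assembles the summary tables, with the package's rounding
## conventions applied throughout.

#' Run the full promoter-capture analysis pipeline
#'
#' Executes, in order: capture profiling (depth, partition lengths, subgenome
#' specificity), haplotype grouping (signatures, shared/unique classes,
#' gene statuses, nullisomic-arm flags, cross-ploidy sharing), structural
#' variant detection (cliff-edge deletions with repeat annotation and
#' hairpin prediction) and TFBS gain/loss scoring for every distinct
#' signature SNP. All stages are deterministic; any missing input path is an
#' error before computation starts.
#'
#' @param config A list with paths `genome`, `gff3`, `targets_tsv`,
#'   `accessions_tsv`, `vcf_dir`, `depth_dir`, `repeats`, `motifs` and
#'   optionally `outdir` (TSV outputs are written there when given), plus
#'   thresholds `min_depth` (10), `min_qual` (30), `af_min` (1-1e-6),
#'   `min_captured_bp` (200), `complete_threshold` (0.5), `min_status_bp`
#'   (100), `tfbs_flank` (5).
#' @return A headline report list: `capture` (per accession x gene
#'   summaries), `subgenome` (specificity table), `polymorphism` (per
#'   accession rates), `self_check`, `groups`, `haplotype_summary`,
#'   `statuses`, `arm_flags`, `sharing`, `deletions` (with repeat
#'   annotation), `tfbs_deltas`, `deletion_tfbs`, `thresholds`.
#' @export
runPipeline <- function(config) {
  defaults <- list(min_depth = 10, min_qual = 30, af_min = 1 - 1e-6,
                   min_captured_bp = 200, complete_threshold = 0.5,
                   min_status_bp = 100, tfbs_flank = 5)
  cfg <- modifyList(defaults, config)
  for (p in c("genome", "gff3", "targets_tsv", "accessions_tsv",
              "vcf_dir", "depth_dir", "repeats", "motifs")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop("pipeline config: missing or nonexistent path for '", p, "'")
    }
  }
  genome <- readDNAStringSet(cfg$genome)
  names(genome) <- sub(" .*", "", names(genome))
  targets <- readTargets(cfg$gff3, cfg$targets_tsv)
  accessions <- read.delim(cfg$accessions_tsv, stringsAsFactors = FALSE)
  repeats <- readDNAStringSet(cfg$repeats)
  names(repeats) <- sub(" .*", "", names(repeats))
  motifs <- loadMotifs(cfg$motifs)
  tg <- targetRanges(targets)
  win <- profileWindows(targets)
  ploidy <- lengths(strsplit(accessions$composition, ","))
  hexIds <- accessions$accession_id[ploidy == 6]

  ## ---- stage 1: capture profiles -------------------------------------------
  profiles <- list(); summaries <- list(); variants <- list()
  for (a in accessions$accession_id) {
    bg <- file.path(cfg$depth_dir, paste0(a, ".bedGraph"))
    vc <- file.path(cfg$vcf_dir, paste0(a, ".vcf"))
    if (!file.exists(bg) || !file.exists(vc)) {
      stop("profile stage: missing VCF/bedGraph for accession ", a)
    }
    profiles[[a]] <- readDepthProfiles(bg, win)
    s <- captureSummaries(profiles[[a]], targets, min_depth = cfg$min_depth)
    s$accession_id <- a
    summaries[[a]] <- s
    v <- readVcfVariants(vc)
    variants[[a]] <- homozygousFilter(v, af_min = cfg$af_min,
                                      min_depth = cfg$min_depth,
                                      min_qual = cfg$min_qual)
  }
  capture <- do.call(rbind, summaries)

  sgRows <- lapply(accessions$accession_id, function(a) {
    exp <- expectedPattern(accessions$composition[
      accessions$accession_id == a])
    fr <- subgenomeCaptureFractions(summaries[[a]], expected = exp,
                                    min_captured_bp = cfg$min_captured_bp)
    data.frame(accession_id = a,
               subgenome = names(fr$counts),
               n_captured = as.integer(fr$counts),
               percent_by_count = as.numeric(fr$percent_by_count),
               percent_by_bases = as.numeric(fr$percent_by_bases),
               expected = paste(exp, collapse = ","),
               observed = paste(fr$observed, collapse = ","),
               verdict = fr$verdict)
  })
  subgenome <- do.call(rbind, sgRows)

  polymorphism <- do.call(rbind, lapply(accessions$accession_id,
                                        function(a) {
    bp <- sum(summaries[[a]]$total_bp)
    data.frame(accession_id = a, n_variants = nrow(variants[[a]]),
               captured_bp = bp,
               rate_per_kbp = if (bp > 0)
                 polymorphismFrequency(nrow(variants[[a]]), bp) else NA_real_)
  }))

  refId <- accessions$accession_id[accessions$category == "reference"][1]
  selfCheck <- referenceSelfCheck(variants[[refId]], targets)

  ## ---- stage 2: haplotypes --------------------------------------------------
  sigRows <- list()
  for (a in accessions$accession_id) {
    s <- summaries[[a]]
    for (i in seq_along(tg)) {
      gid <- tg$gene_id[i]
      row <- buildSignature(variants[[a]], tg[i],
                            s$captured_fraction[s$gene_id == gid],
                            complete_threshold = cfg$complete_threshold)
      row$accession_id <- a
      sigRows[[length(sigRows) + 1L]] <- row
    }
  }
  signatures <- do.call(rbind, sigRows)

  hexSig <- signatures[signatures$accession_id %in% hexIds, , drop = FALSE]
  relSig <- signatures[!signatures$accession_id %in% hexIds, , drop = FALSE]
  groups <- do.call(rbind, lapply(split(hexSig, hexSig$gene_id),
                                  function(sg) {
    i <- which(tg$gene_id == sg$gene_id[1])
    groupHaplotypes(sg, subgenome = tg$subgenome[i],
                    comparison_set = hexIds, gene_id = sg$gene_id[1])
  }))
  rownames(groups) <- NULL

  statuses <- do.call(rbind, lapply(accessions$accession_id, function(a) {
    s <- summaries[[a]]
    data.frame(accession_id = a, gene_id = s$gene_id,
               status = callGeneStatus(s$promoter_bp, s$exon_intron_bp,
                                       min_bp = cfg$min_status_bp))
  }))
  armFlags <- detectMissingArmClusters(statuses, targets)
  sharing <- crossPloidySharing(hexSig, relSig)
  hapSummary <- summarizeHaplotypes(groups,
                                    n_genes = length(tg),
                                    comparison_size = length(hexIds))

  ## ---- stage 3: structural variants ----------------------------------------
  delRows <- list(); delAnnot <- list(); delTfbs <- list()
  chromChar <- lapply(as.character(genome), .charVec)
  for (a in accessions$accession_id) {
    for (gid in tg$gene_id) {
      d <- profiles[[a]][[gid]]
      res <- detectCliffDeletions(d, flank_depth = cfg$min_depth)
      if (!nrow(res$deletions)) next
      w <- win[gid]
      for (k in seq_len(nrow(res$deletions))) {
        gs <- start(w) + res$deletions$start[k] - 1L
        ge <- start(w) + res$deletions$end[k] - 1L
        cn <- as.character(seqnames(w))
        delSeq <- paste(chromChar[[cn]][gs:ge], collapse = "")
        key <- paste(cn, gs, ge, sep = ":")
        if (is.null(delAnnot[[key]])) {
          ann <- annotateDeletionRepeats(delSeq, repeats)
          hp <- findHairpin(delSeq)
          tf <- deletionTfbsContent(delSeq, motifs)
          delAnnot[[key]] <- list(ann = ann, hp = hp, tfbs = tf)
        }
        ann <- delAnnot[[key]]
        delRows[[length(delRows) + 1L]] <- data.frame(
          accession_id = a, gene_id = gid, chrom = cn,
          start = gs, end = ge, size = res$deletions$size[k],
          class = res$deletions$class[k],
          repeat_names = paste(unique(ann$ann$hits$name), collapse = "+"),
          chimera = ann$ann$chimera,
          has_nested = any(ann$ann$hits$nested),
          hairpin_stem = if (is.null(ann$hp)) NA_integer_ else
            ann$hp$stem_len,
          n_tfbs = ann$tfbs$count)
      }
    }
  }
  deletions <- if (length(delRows)) do.call(rbind, delRows) else
    data.frame(accession_id = character(0), gene_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               size = integer(0), class = character(0),
               repeat_names = character(0), chimera = logical(0),
               has_nested = logical(0), hairpin_stem = integer(0),
               n_tfbs = integer(0))

  ## ---- stage 4: TFBS deltas for distinct signature SNPs --------------------
  tfbsRows <- list()
  distinctSnps <- unique(do.call(rbind, lapply(
    split(groups, seq_len(nrow(groups))), function(g) {
      if (g$signature == "") return(NULL)
      parts <- strsplit(g$signature, ";", fixed = TRUE)[[1]]
      pos <- as.integer(sub(":.*", "", parts))
      ref <- sub(".*?:(.*)>.*", "\\1", parts)
      alt <- sub(".*>", "", parts)
      isSnp <- nchar(ref) == 1 & nchar(alt) == 1
      if (!any(isSnp)) return(NULL)
      data.frame(gene_id = g$gene_id, label = g$label,
                 pos = pos[isSnp], ref = ref[isSnp], alt = alt[isSnp])
    })))
  if (!is.null(distinctSnps) && nrow(distinctSnps)) {
    for (k in seq_len(nrow(distinctSnps))) {
      gid <- distinctSnps$gene_id[k]
      i <- which(tg$gene_id == gid)
      cn <- as.character(seqnames(tg[i]))
      tseq <- paste(chromChar[[cn]][start(tg[i]):end(tg[i])], collapse = "")
      local <- distinctSnps$pos[k] - start(tg[i]) + 1L
      delta <- snpWindowDelta(tseq, local, distinctSnps$alt[k], motifs,
                              flank = cfg$tfbs_flank)
      tfbsRows[[length(tfbsRows) + 1L]] <- data.frame(
        gene_id = gid, label = distinctSnps$label[k],
        atg_offset = atgOffset(distinctSnps$pos[k], tg$atg_pos[i],
                               as.character(strand(tg[i]))),
        n_wt = nrow(delta$wt_hits), n_alt = nrow(delta$alt_hits),
        gained = paste(delta$gained, collapse = ","),
        lost = paste(delta$lost, collapse = ","))
    }
  }
  tfbsDeltas <- if (length(tfbsRows)) do.call(rbind, tfbsRows) else
    data.frame(gene_id = character(0), label = character(0),
               atg_offset = integer(0), n_wt = integer(0),
               n_alt = integer(0), gained = character(0),
               lost = character(0))

  report <- list(capture = capture, subgenome = subgenome,
                 polymorphism = polymorphism, self_check = selfCheck,
                 signatures = signatures, groups = groups,
                 haplotype_summary = hapSummary, statuses = statuses,
                 arm_flags = armFlags, sharing = sharing,
                 deletions = deletions, tfbs_deltas = tfbsDeltas,
                 thresholds = cfg[names(defaults)])

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("capture", "subgenome", "polymorphism", "groups",
                 "statuses", "arm_flags", "deletions", "tfbs_deltas")) {
      write.table(report[[nm]],
                  file.path(cfg$outdir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(sharing$candidates,
                file.path(cfg$outdir, "introgression_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Per-trait roll-up of the target catalogue
#'
#' Aggregates a targets table by trait: number of distinct genes
#' (homoeologous groups), total homoeologues, and counts of groups by
#' subgenome composition (`ABD` full triads, `AB`, `AD`, `BD`, singletons
#' `A`, `B`, `D`, everything else under `other`), plus a grand-total row.
#'
#' @param targets A targets data.frame (or [TargetSet-class]) with
#'   `trait_tag`, `homoeo_group_id`, `subgenome` columns.
#' @return A data.frame, one row per trait plus a `Total` row.
#' @export
traitRollup <- function(targets) {
  if (is(targets, "TargetSet")) {
    tg <- targetRanges(targets)
    targets <- data.frame(trait_tag = tg$trait_tag,
                          homoeo_group_id = tg$homoeo_group_id,
                          subgenome = tg$subgenome)
  }
  if (!nrow(targets)) {
    return(data.frame(trait = "Total", n_genes = 0L, n_homoeologues = 0L,
                      ABD = 0L, AB = 0L, AD = 0L, BD = 0L,
                      A = 0L, B = 0L, D = 0L, other = 0L))
  }
  targets$trait <- sub("-.*", "", targets$trait_tag)
  compOf <- vapply(split(targets$subgenome, targets$homoeo_group_id),
                   function(s) paste(sort(unique(s)), collapse = ""),
                   character(1))
  groupTrait <- vapply(split(targets$trait, targets$homoeo_group_id),
                       function(t) t[1], character(1))
  cats <- c("ABD", "AB", "AD", "BD", "A", "B", "D")
  rows <- lapply(sort(unique(targets$trait)), function(tr) {
    gids <- names(groupTrait)[groupTrait == tr]
    comp <- compOf[gids]
    cnt <- vapply(cats, function(cc) sum(comp == cc), integer(1))
    data.frame(trait = tr,
               n_genes = length(gids),
               n_homoeologues = sum(targets$trait == tr),
               as.list(cnt),
               other = sum(!comp %in% cats))
  })
  out <- do.call(rbind, rows)
  total <- data.frame(trait = "Total",
                      n_genes = sum(out$n_genes),
                      n_homoeologues = sum(out$n_homoeologues),
                      as.list(colSums(out[, cats, drop = FALSE])),
                      other = sum(out$other))
  rbind(out, total)
}

#' Global pairwise identity between two target sequences
#'
#' Needleman-Wunsch global alignment with unit scores (match +1, mismatch
#' -1, gap -2); reports identities over the aligned length (gaps included)
#' and the rounded percentage, the convention used when comparing target
#' sequences between assembly versions.
#'
#' @param seq_a,seq_b Character scalars (non-empty).
#' @return A list with `identities`, `aligned_length`, `percent`.
#' @export
pairwiseTargetIdentity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("pairwiseTargetIdentity: empty sequence")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- pairwiseAlignment(DNAString(seq_a), DNAString(seq_b),
                           substitutionMatrix = mat,
                           gapOpening = 0, gapExtension = 2,
                           type = "global")
  pa <- as.character(alignedPattern(aln))
  alnLen <- nchar(pa)
  ident <- nmatch(aln)
  list(identities = ident, aligned_length = alnLen,
       percent = percentRounded(ident, alnLen, 0))
}
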