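## Homozygous-variant haplotype analysis: signatures per accession x target,
## grouping into shared/unique/reference-identical haplotypes, missing-gene
## and nullisomic-arm calls, and cross-ploidy sharing (introgression
## candidates).

#' Filter variants to high-confidence homozygous calls
#'
#' Keeps variants with allele frequency at least `af_min` (default 1 minus a
#' small epsilon absorbing float representation of 1.0), read depth at least
#' `min_depth`, quality at least `min_qual`, and InDel length at most
#' `max_indel` (larger events are depth-space territory, see
#' [detectCliffDeletions()]).
#'
#' @param variants Variant table from [readVcfVariants()].
#' @param af_min,min_depth,min_qual,max_indel Filter thresholds (defaults
#'   1-1e-6, 10, 30, 20).
#' @return The filtered variant table.
#' @export
homozygousFilter <- function(variants, af_min = 1 - 1e-6, min_depth = 10,
                             min_qual = 30, max_indel = 20) {
  keep <- !is.na(variants$af) & variants$af >= af_min &
    !is.na(variants$depth) & variants$depth >= min_depth &
    !is.na(variants$qual) & variants$qual >= min_qual &
    variants$indel_len <= max_indel
  variants[keep, , drop = FALSE]
}

.sigKey <- function(v) {
  if (!nrow(v)) return("")
  v <- v[order(v$pos), , drop = FALSE]
  paste(sprintf("%d:%s>%s", v$pos, v$ref, v$alt), collapse = ";")
}

#' Build the homozygous-variant signature of one accession at one target
#'
#' The signature is the position-sorted list of homozygous SNPs and small
#' InDels inside the target window. Accessions whose captured fraction of
#' the target is below `complete_threshold` are flagged incomplete and are
#' excluded from grouping by default (absence of evidence is not evidence of
#' reference identity).
#'
#' @param variants Homozygous-filtered variant table for one accession.
#' @param target A length-1 GRanges (one row of [targetRanges()]).
#' @param captured_fraction Fraction of the target captured at the depth
#'   threshold.
#' @param complete_threshold Minimum captured fraction for a signature to be
#'   complete (default 0.5).
#' @return A one-row data.frame: `gene_id`, `signature` (canonical
#'   `pos:REF>ALT` string, empty = reference-identical), `n_snps`,
#'   `n_indels`, `complete`.
#' @export
buildSignature <- function(variants, target, captured_fraction,
                           complete_threshold = 0.5) {
  inWin <- variants[variants$chrom == as.character(seqnames(target)) &
                      variants$pos >= start(target) &
                      variants$pos <= end(target), , drop = FALSE]
  data.frame(gene_id = target$gene_id,
             signature = .sigKey(inWin),
             n_snps = sum(inWin$vtype == "SNP"),
             n_indels = sum(inWin$vtype == "InDel"),
             complete = captured_fraction >= complete_threshold,
             stringsAsFactors = FALSE)
}

#' Group identical signatures into haplotypes for one gene
#'
#' Identical complete signatures are merged into haplotype groups. Labels are
#' the subgenome letter plus a rank: rank 1 is the reference-identical group
#' when present, then groups in order of decreasing member count, ties broken
#' by first variant position and then by the signature string. A group is
#' `shared` when at least two members belong to the comparison set (by
#' convention the hexaploid accessions), otherwise `unique`.
#'
#' @param signatures A data.frame with `accession_id`, `signature`,
#'   `complete` (and optionally `n_snps`, `n_indels`) for one gene.
#' @param subgenome Subgenome letter used in labels.
#' @param comparison_set Accession ids over which the shared/unique rule is
#'   evaluated (default: all accessions present).
#' @param gene_id Gene identifier recorded in the output.
#' @return A data.frame of haplotype groups: `gene_id`, `label`,
#'   `signature`, `n_members`, `members` (comma-joined, sorted), `n_shared
#'   members in the comparison set`, `n_snps`, `n_indels`, `class`,
#'   `ref_identical`.
#' @export
groupHaplotypes <- function(signatures, subgenome = "A",
                            comparison_set = NULL, gene_id = NULL) {
  sig <- signatures[signatures$complete, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(gene_id = character(0), label = character(0),
                      signature = character(0), n_members = integer(0),
                      members = character(0), n_comparison = integer(0),
                      n_snps = integer(0), n_indels = integer(0),
                      class = character(0), ref_identical = logical(0)))
  }
  if (is.null(comparison_set)) comparison_set <- sig$accession_id
  if (is.null(gene_id)) {
    gene_id <- if ("gene_id" %in% colnames(sig)) sig$gene_id[1] else NA
  }
  keys <- split(sig$accession_id, sig$signature)
  sigStr <- names(keys)
  firstPos <- vapply(sigStr, function(s) {
    if (s == "") return(-1L)
    as.integer(sub(":.*", "", strsplit(s, ";", fixed = TRUE)[[1]][1]))
  }, integer(1))
  nMembers <- lengths(keys)
  ord <- order(sigStr != "", -nMembers, firstPos, sigStr)
  sigStr <- sigStr[ord]; keys <- keys[ord]
  nMembers <- nMembers[ord]; firstPos <- firstPos[ord]
  nComp <- vapply(keys, function(m)
    sum(m %in% comparison_set), integer(1))
  nv <- lapply(sigStr, function(s) {
    if (s == "") return(c(0L, 0L))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    refs <- sub(".*?:(.*)>.*", "\\1", parts)
    alts <- sub(".*>", "", parts)
    isSnp <- nchar(refs) == 1 & nchar(alts) == 1
    c(sum(isSnp), sum(!isSnp))
  })
  data.frame(gene_id = gene_id,
             label = paste0(subgenome, seq_along(sigStr)),
             signature = sigStr,
             n_members = as.integer(nMembers),
             members = vapply(keys, function(m)
               paste(sort(m), collapse = ","), character(1)),
             n_comparison = nComp,
             n_snps = vapply(nv, `[`, integer(1), 1),
             n_indels = vapply(nv, `[`, integer(1), 2),
             class = ifelse(nComp >= 2, "shared", "unique"),
             ref_identical = sigStr == "",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene capture status of one accession at one gene
#'
#' @param promoter_bp Captured bases in the target (promoter + 5'UTR) window.
#' @param cds_bp Captured bases in the exon/intron (CDS-side) window.
#' @param min_bp Minimum captured bases to count a window as present
#'   (default 100).
#' @return One of `captured`, `missing_gene` (neither window captured),
#'   `promoter_absent_cds_present`.
#' @export
callGeneStatus <- function(promoter_bp, cds_bp, min_bp = 100) {
  ifelse(promoter_bp < min_bp & cds_bp < min_bp, "missing_gene",
         ifelse(promoter_bp < min_bp, "promoter_absent_cds_present",
                "captured"))
}

#' Flag chromosome arms where every target of an accession is missing
#'
#' An accession x arm pair is flagged (nullisomic candidate) when all of the
#' arm's targets (at least `min_genes` of them) are `missing_gene` while the
#' sister arm of the same chromosome retains at least one captured target.
#'
#' @param statuses A data.frame with `accession_id`, `gene_id`, `status`.
#' @param targetset A [TargetSet-class] whose targets carry `arm` labels
#'   (e.g. "1BS"/"1BL").
#' @param min_genes Minimum targets on the arm for a flag (default 5).
#' @return A data.frame `accession_id`, `arm`, `n_missing`.
#' @export
detectMissingArmClusters <- function(statuses, targetset, min_genes = 5) {
  tg <- targetRanges(targetset)
  armOf <- setNames(tg$arm, tg$gene_id)
  chromOf <- setNames(as.character(seqnames(tg)), tg$gene_id)
  statuses$arm <- armOf[statuses$gene_id]
  statuses$chrom <- chromOf[statuses$gene_id]
  out <- list()
  for (a in unique(statuses$accession_id)) {
    st <- statuses[statuses$accession_id == a, , drop = FALSE]
    for (arm in unique(st$arm)) {
      onArm <- st[st$arm == arm, , drop = FALSE]
      if (nrow(onArm) < min_genes) next
      if (!all(onArm$status == "missing_gene")) next
      sister <- st[st$chrom == onArm$chrom[1] & st$arm != arm, ,
                   drop = FALSE]
      if (nrow(sister) && any(sister$status == "captured")) {
        out[[length(out) + 1L]] <- data.frame(
          accession_id = a, arm = arm, n_missing = nrow(onArm))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(accession_id = character(0), arm = character(0),
                      n_missing = integer(0)))
  }
  do.call(rbind, out)
}

#' Cross-ploidy haplotype sharing (introgression candidates)
#'
#' For every gene and relative (diploid/tetraploid) accession whose complete
#' signature is non-empty, reports the hexaploid accessions carrying the
#' identical signature. Empty (reference-identical) relative signatures are
#' uninformative and excluded. Identity covers the full signature, InDels
#' included.
#'
#' @param hex_signatures Data.frame `gene_id`, `accession_id`, `signature`,
#'   `complete` for the hexaploid comparison set.
#' @param rel_signatures Same, for the relative accessions.
#' @return A list with `candidates` (`gene_id`, `relative`, `recipient`,
#'   `signature`) and `percent_by_relative` (percent of genes with at least
#'   one sharing per relative, 1 decimal).
#' @export
crossPloidySharing <- function(hex_signatures, rel_signatures) {
  hx <- hex_signatures[hex_signatures$complete, , drop = FALSE]
  rl <- rel_signatures[rel_signatures$complete &
                         rel_signatures$signature != "", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rl))) {
    match <- hx[hx$gene_id == rl$gene_id[i] &
                  hx$signature == rl$signature[i], , drop = FALSE]
    if (nrow(match)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rl$gene_id[i], relative = rl$accession_id[i],
        recipient = match$accession_id, signature = rl$signature[i])
    }
  }
  candidates <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), relative = character(0),
               recipient = character(0), signature = character(0))
  nGenes <- length(unique(hex_signatures$gene_id))
  pct <- vapply(unique(rel_signatures$accession_id), function(r) {
    g <- unique(candidates$gene_id[candidates$relative == r])
    percentRounded(length(g), nGenes, 1)
  }, numeric(1))
  list(candidates = candidates, percent_by_relative = pct)
}

#' Headline haplotype statistics
#'
#' @param groups Haplotype groups for all genes (rbind of
#'   [groupHaplotypes()] outputs).
#' @param n_genes Total number of analysed genes.
#' @param comparison_size Number of accessions in the comparison set.
#' @return A list with `per_gene` (shared/unique counts per gene),
#'   `per_accession_unique` (unique-haplotype count and percent of genes per
#'   accession), `percent_reference_identical_only` (percent of genes whose
#'   sole haplotype is the reference-identical one), and `snp_histogram`
#'   (mean occurrence of x-SNP haplotypes per gene, x = 1..15+).
#' @export
summarizeHaplotypes <- function(groups, n_genes = NULL,
                                comparison_size = NULL) {
  if (is.null(n_genes)) n_genes <- length(unique(groups$gene_id))
  perGene <- do.call(rbind, lapply(split(groups, groups$gene_id),
                                   function(g) data.frame(
    gene_id = g$gene_id[1],
    n_shared = sum(g$class == "shared"),
    n_unique = sum(g$class == "unique"),
    n_haplotypes = nrow(g),
    sole_ref_identical = nrow(g) == 1 && g$ref_identical[1])))
  uniqAcc <- table(unlist(strsplit(
    groups$members[groups$class == "unique"], ",", fixed = TRUE)))
  perAcc <- data.frame(accession_id = names(uniqAcc),
                       n_unique = as.integer(uniqAcc),
                       percent_of_genes = percentRounded(
                         as.integer(uniqAcc), n_genes, 0),
                       row.names = NULL)
  snpCounts <- pmin(groups$n_snps + groups$n_indels, 15L)
  hist <- vapply(1:15, function(k)
    sum(snpCounts == k) / n_genes, numeric(1))
  names(hist) <- c(1:14, "15+")
  list(per_gene = perGene[order(perGene$gene_id), ],
       per_accession_unique = perAcc[order(-perAcc$n_unique), ],
       percent_reference_identical_only = percentRounded(
         sum(perGene$sole_ref_identical), n_genes, 0),
       snp_histogram = hist)
}
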