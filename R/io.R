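## Readers and writers for the standard interchange formats: targets
## (GFF3 + TSV), variants (VCF 4.x) and per-base capture depth (bedGraph).
## Coordinates are 1-based closed GRanges internally; rtracklayer performs the
## 0-based half-open conversion at BED/bedGraph boundaries.

#' Read the target catalogue from a targets TSV and a GFF3 annotation
#'
#' The TSV names one homoeo-allele target per row (`gene_id`, `trait_tag`,
#' `homoeo_group_id`, `subgenome`, `chrom`, `strand`, `atg_pos`, `span`, and
#' optionally `arm`); the target interval is derived from the ATG position,
#' strand and span (promoter + 5'UTR immediately upstream of the ATG).
#' Annotation partitions (promoter, five_utr, exon, intron) are derived from
#' the GFF3 gene models: the `five_prime_UTR` feature splits the target, and
#' `exon` features downstream of the ATG define the exon/intron partitions.
#'
#' @param gff3_path Path to a GFF3 file containing gene models (features of
#'   type `gene`, `five_prime_UTR`, `exon` with `ID`/`Parent` linking to the
#'   gene identifiers).
#' @param targets_tsv_path Path to the targets TSV.
#' @return A [TargetSet-class], ordered by chromosome then start.
#' @export
readTargets <- function(gff3_path, targets_tsv_path) {
  tsv <- read.delim(targets_tsv_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "trait_tag", "homoeo_group_id", "subgenome",
            "chrom", "strand", "atg_pos", "span")
  miss <- setdiff(need, colnames(tsv))
  if (length(miss)) {
    stop("targets TSV missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"arm" %in% colnames(tsv)) tsv$arm <- NA_character_
  if (any(tsv$span < 1) || any(is.na(tsv$atg_pos))) {
    stop("malformed target interval: span and atg_pos must be positive")
  }
  gff <- import(gff3_path)
  genes <- gff[gff$type == "gene"]
  geneIdsGff <- genes$ID
  absent <- setdiff(tsv$gene_id, geneIdsGff)
  if (length(absent)) {
    stop("no gene model in GFF3 for: ", paste(absent, collapse = ", "))
  }
  plus <- tsv$strand == "+"
  startv <- ifelse(plus, tsv$atg_pos - tsv$span, tsv$atg_pos + 1L)
  endv <- ifelse(plus, tsv$atg_pos - 1L, tsv$atg_pos + tsv$span)
  if (any(startv < 1)) stop("malformed target interval: extends before chromosome start")
  gr <- GRanges(tsv$chrom, IRanges(startv, endv), strand = tsv$strand,
                gene_id = tsv$gene_id, trait_tag = tsv$trait_tag,
                homoeo_group_id = tsv$homoeo_group_id,
                subgenome = tsv$subgenome,
                atg_pos = as.integer(tsv$atg_pos), arm = tsv$arm)
  parentOf <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  parts <- lapply(seq_along(gr), function(i) {
    gid <- gr$gene_id[i]
    mine <- !is.na(parentOf) & parentOf == gid
    .derivePartitions(as.character(seqnames(gr))[i],
                      IRanges(start(gr)[i], end(gr)[i]),
                      ranges(gff)[gff$type == "five_prime_UTR" & mine],
                      ranges(gff)[gff$type == "exon" & mine])
  })
  names(parts) <- gr$gene_id
  ord <- order(as.character(seqnames(gr)), start(gr))
  ts <- new("TargetSet", targets = gr[ord],
            partitions = GRangesList(parts)[gr$gene_id[ord]])
  ts
}

## Partition one target: promoter/five_utr inside the target interval,
## exon/intron downstream (transcript side) taken from GFF3 exon features.
## Plain IRanges arithmetic; the GRanges is assembled once at the end.
.derivePartitions <- function(chrom, target, utr, exons) {
  utrIn <- reduce(intersect(utr, target))
  prom <- reduce(setdiff(target, utrIn))
  exn <- reduce(setdiff(exons, target))
  intr <- IRanges()
  if (length(exons)) {
    body <- range(exons)
    intr <- setdiff(setdiff(body, exons), target)
  }
  ir <- c(prom, utrIn, exn, intr)
  part <- rep(c("promoter", "five_utr", "exon", "intron"),
              c(length(prom), length(utrIn), length(exn), length(intr)))
  out <- GRanges(chrom, ir, part = part)
  sort(out)
}

#' Read homozygosity-annotated variants from a VCF file
#'
#' Parses a VCF 4.x file into a flat variant table, one row per ALT allele.
#' Allele frequency and depth are read from configurable INFO keys
#' (default `AF` and `DP`). Variants are typed as `SNP` when both alleles
#' have length 1, otherwise `InDel`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param af_key,dp_key INFO keys for allele frequency and read depth.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `vtype`,
#'   `indel_len` (absolute length difference), `af`, `qual`, `depth`.
#' @export
readVcfVariants <- function(path, af_key = "AF", dp_key = "DP") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fx)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), indel_len = integer(0),
                      af = numeric(0), qual = numeric(0), depth = integer(0)))
  }
  ## one row per ALT allele
  alts <- strsplit(fx$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  idx <- rep(seq_len(nrow(fx)), n)
  afv <- .infoField(fx$INFO, af_key)
  dpv <- .infoField(fx$INFO, dp_key)
  if (all(is.na(afv))) {
    stop("allele-frequency INFO key not found in VCF: ", af_key)
  }
  afs <- strsplit(ifelse(is.na(afv), "", afv), ",", fixed = TRUE)
  afOne <- function(i, k) {
    a <- afs[[i]]
    if (!length(a)) NA_real_ else as.numeric(a[min(k, length(a))])
  }
  altIdx <- sequence(n)
  out <- data.frame(
    chrom = fx$CHROM[idx],
    pos = as.integer(fx$POS[idx]),
    ref = fx$REF[idx],
    alt = unlist(alts),
    stringsAsFactors = FALSE)
  out$indel_len <- abs(nchar(out$ref) - nchar(out$alt))
  out$vtype <- ifelse(nchar(out$ref) == 1 & nchar(out$alt) == 1,
                      "SNP", "InDel")
  out$af <- mapply(afOne, idx, altIdx)
  out$qual <- suppressWarnings(as.numeric(fx$QUAL[idx]))
  out$depth <- suppressWarnings(as.integer(dpv[idx]))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.infoField <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Write homozygous variants as a minimal VCF 4.2 file
#'
#' Deterministic plain-text VCF emitter used by the panel simulator; the
#' records round-trip exactly through [readVcfVariants()].
#'
#' @param variants A data.frame with `chrom`, `pos`, `ref`, `alt`, `af`,
#'   `qual`, `depth`.
#' @param path Output file path.
#' @param sample_id Sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
writeVcfVariants <- function(variants, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=promcap ", as.character(utils::packageVersion("promcap"))),
           paste0("##sample=", sample_id),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  lines <- hdr
  if (nrow(v)) {
    recs <- paste(v$chrom, v$pos, ".", v$ref, v$alt,
                  format(v$qual, trim = TRUE),
                  "PASS",
                  paste0("AF=", format(v$af, trim = TRUE), ";DP=", v$depth),
                  sep = "\t")
    lines <- c(hdr, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-base capture depth profiles from a bedGraph file
#'
#' Expands bedGraph runs into per-base depth vectors over the supplied target
#' windows. Bases not covered by any bedGraph interval get depth 0; intervals
#' falling entirely outside all windows are ignored. Overlapping intervals
#' with contradictory values are an error.
#'
#' @param path Path to a bedGraph file (0-based half-open on disk).
#' @param windows A named [GenomicRanges::GRanges] of profile windows, one per
#'   gene (names = gene_id), e.g. target plus flanking CDS window.
#' @return A named list (by window name) of integer depth vectors, one value
#'   per base of the window, with attributes `chrom` and `start`.
#' @export
readDepthProfiles <- function(path, windows) {
  if (is.null(names(windows)) || anyDuplicated(names(windows))) {
    stop("windows must be uniquely named by gene")
  }
  gr <- import(path, format = "bedGraph")
  if (length(gr)) {
    ov <- findOverlaps(gr, gr)
    ov <- ov[queryHits(ov) < subjectHits(ov)]
    if (length(ov) &&
        any(gr$score[queryHits(ov)] != gr$score[subjectHits(ov)])) {
      stop("bedGraph contains overlapping intervals with contradictory depth")
    }
  }
  wChrom <- as.character(seqnames(windows))
  wStart <- start(windows); wEnd <- end(windows)
  out <- setNames(lapply(seq_along(windows), function(i) {
    d <- integer(wEnd[i] - wStart[i] + 1L)
    attr(d, "chrom") <- wChrom[i]
    attr(d, "start") <- wStart[i]
    d
  }), names(windows))
  if (length(gr)) {
    gStart <- start(gr); gEnd <- end(gr)
    gScore <- as.integer(gr$score)
    hits <- suppressWarnings(
      findOverlaps(gr, windows, ignore.strand = TRUE))
    q <- queryHits(hits); w <- subjectHits(hits)
    lo <- pmax(gStart[q], wStart[w]) - wStart[w] + 1L
    hi <- pmin(gEnd[q], wEnd[w]) - wStart[w] + 1L
    for (k in seq_along(q)) {
      out[[w[k]]][lo[k]:hi[k]] <- gScore[q[k]]
    }
  }
  out
}

#' Write a depth vector set as bedGraph
#'
#' Run-length encodes per-chromosome depth vectors; zero-depth runs are
#' omitted (absence of an interval means depth 0).
#'
#' @param depths Named list (by chromosome) of integer per-base depth vectors
#'   covering each chromosome from base 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(depths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(depths)) {
    r <- rle(as.integer(depths[[chrom]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths # 0-based starts
    keep <- r$values > 0
    if (any(keep)) {
      writeLines(paste(chrom, starts[keep], ends[keep], r$values[keep],
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Profile windows for a TargetSet
#'
#' The depth-profile window of a gene is its target interval extended to the
#' end of the annotated gene body (captured exon/intron sequence is reported
#' separately by [partitionLengths()]).
#'
#' @param targetset A [TargetSet-class].
#' @return A named GRanges (names = gene_id).
#' @export
profileWindows <- function(targetset) {
  tg <- targetRanges(targetset)
  parts <- targetPartitions(targetset)[tg$gene_id]
  pu <- unlist(parts, use.names = FALSE)
  grp <- rep(seq_along(parts), lengths(parts))
  pMin <- tapply(start(pu), grp, min)
  pMax <- tapply(end(pu), grp, max)
  lo <- start(tg); hi <- end(tg)
  idx <- as.integer(names(pMin))
  lo[idx] <- pmin(lo[idx], pMin)
  hi[idx] <- pmax(hi[idx], pMax)
  win <- GRanges(seqnames(tg), IRanges(lo, hi))
  names(win) <- tg$gene_id
  win
}
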