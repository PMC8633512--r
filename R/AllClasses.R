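## S4 containers for the central data objects: the target catalogue, the
## designed probe set, the IUPAC motif library and the simulated panel.

setOldClass("data.frame")

#' TargetSet: catalogue of promoter/5'UTR capture targets
#'
#' Holds one record per homoeo-allele target: the genomic target interval
#' (promoter + 5'UTR upstream of the annotated ATG), gene/trait identifiers,
#' the subgenome assignment and chromosome-arm label, plus the annotation
#' partitions (promoter, five_utr, exon, intron) derived from the gene models.
#'
#' @slot targets A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `trait_tag`, `homoeo_group_id`, `subgenome`, `atg_pos`, `arm`.
#' @slot partitions A [GenomicRanges::GRangesList] named by `gene_id`; each
#'   element carries a metadata column `part` with values in
#'   `promoter`, `five_utr`, `exon`, `intron`.
#' @export
setClass("TargetSet",
         slots = c(targets = "GRanges", partitions = "GRangesList"))

setValidity("TargetSet", function(object) {
  need <- c("gene_id", "trait_tag", "homoeo_group_id", "subgenome",
            "atg_pos", "arm")
  miss <- setdiff(need, colnames(mcols(object@targets)))
  if (length(miss)) {
    return(paste("missing target metadata columns:",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(mcols(object@targets)$gene_id)) {
    return("gene_id values must be unique")
  }
  if (!all(names(object@partitions) %in% mcols(object@targets)$gene_id)) {
    return("partitions must be named by known gene_id")
  }
  TRUE
})

#' @describeIn TargetSet Number of targets.
#' @param x,object A `TargetSet`.
#' @export
setMethod("length", "TargetSet", function(x) length(x@targets))

#' Accessors for TargetSet
#'
#' `geneIds()` returns the target gene identifiers, `targetRanges()` the
#' target intervals as a GRanges and `targetPartitions()` the per-gene
#' annotation partitions.
#'
#' @param x A `TargetSet`.
#' @return Character vector, GRanges or GRangesList respectively.
#' @export
geneIds <- function(x) mcols(x@targets)$gene_id

#' @rdname geneIds
#' @export
targetRanges <- function(x) x@targets

#' @rdname geneIds
#' @export
targetPartitions <- function(x) x@partitions

setMethod("show", "TargetSet", function(object) {
  tg <- object@targets
  cat("TargetSet with", length(tg), "targets on",
      length(unique(as.character(seqnames(tg)))), "chromosomes\n")
  cat("  subgenomes:",
      paste(sort(unique(mcols(tg)$subgenome)), collapse = ", "), "\n")
  cat("  traits:",
      paste(sort(unique(sub("-.*", "", mcols(tg)$trait_tag))),
            collapse = ", "), "\n")
})

#' ProbeSet: tiled capture probe candidates with filtering status
#'
#' One row per 120-nt probe candidate. After [filterProbes()] the `status`
#' column is one of `retained`, `removed_masked`, `removed_multihit`.
#'
#' @slot probes A data.frame with columns `probe_id`, `gene_id`, `chrom`,
#'   `start`, `end` (1-based closed), `sequence`, `masked_fraction`,
#'   `hyb_hits`, `status`.
#' @export
setClass("ProbeSet", slots = c(probes = "data.frame"))

setValidity("ProbeSet", function(object) {
  need <- c("probe_id", "gene_id", "chrom", "start", "end", "sequence",
            "masked_fraction", "hyb_hits", "status")
  miss <- setdiff(need, colnames(object@probes))
  if (length(miss)) {
    return(paste("missing probe columns:", paste(miss, collapse = ", ")))
  }
  w <- object@probes$end - object@probes$start + 1L
  if (length(w) && any(w != nchar(object@probes$sequence))) {
    return("probe interval width must equal sequence length")
  }
  ok <- object@probes$status %in%
    c(NA, "retained", "removed_masked", "removed_multihit")
  if (!all(ok)) return("invalid probe status")
  TRUE
})

#' @describeIn ProbeSet Number of probes.
#' @param x,object A `ProbeSet`.
#' @export
setMethod("length", "ProbeSet", function(x) nrow(x@probes))

#' Accessors for ProbeSet
#'
#' `probeTable()` returns the full probe table; `retainedProbes()` only the
#' probes that survived masking and specificity filtering.
#'
#' @param x A `ProbeSet`.
#' @return A data.frame.
#' @export
probeTable <- function(x) x@probes

#' @rdname probeTable
#' @export
retainedProbes <- function(x) {
  x@probes[!is.na(x@probes$status) & x@probes$status == "retained", ,
           drop = FALSE]
}

setMethod("show", "ProbeSet", function(object) {
  p <- object@probes
  cat("ProbeSet with", nrow(p), "probes for",
      length(unique(p$gene_id)), "targets\n")
  if (all(!is.na(p$status))) {
    tab <- table(p$status)
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  } else {
    cat("  status: not yet filtered\n")
  }
})

#' MotifLibrary: IUPAC consensus transcription-factor binding motifs
#'
#' @slot motifs A data.frame with columns `name`, `species` (semicolon-joined
#'   list of source species after deduplication) and `consensus` (IUPAC
#'   nucleotide string).
#' @export
setClass("MotifLibrary", slots = c(motifs = "data.frame"))

setValidity("MotifLibrary", function(object) {
  need <- c("name", "species", "consensus")
  miss <- setdiff(need, colnames(object@motifs))
  if (length(miss)) {
    return(paste("missing motif columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(object@motifs) && any(nchar(object@motifs$consensus) == 0)) {
    return("empty motif consensus")
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(object@motifs$consensus))
  if (any(bad)) {
    return(paste("invalid IUPAC consensus in rows:",
                 paste(which(bad), collapse = ", ")))
  }
  TRUE
})

#' @describeIn MotifLibrary Number of motifs.
#' @param x,object A `MotifLibrary`.
#' @export
setMethod("length", "MotifLibrary", function(x) nrow(x@motifs))

#' Accessor for MotifLibrary
#' @param x A `MotifLibrary`.
#' @return The motif data.frame.
#' @export
motifTable <- function(x) x@motifs

setMethod("show", "MotifLibrary", function(object) {
  cat("MotifLibrary with", nrow(object@motifs), "motifs, widths",
      paste(range(nchar(object@motifs$consensus)), collapse = "-"), "bp\n")
})

#' WheatPanelSim: a simulated mixed-ploidy capture panel with planted truth
#'
#' Container returned by [simulatePanel()]: the synthetic reference genome and
#' target catalogue, the repeat library, the accession panel, each accession's
#' planted edits and the ground-truth tables used by recovery tests.
#'
#' @slot genome A [Biostrings::DNAStringSet], one pseudo-chromosome per
#'   subgenome.
#' @slot targets A [TargetSet-class].
#' @slot repeats A [Biostrings::DNAStringSet] repeat library (outer element
#'   and nested MITE stored separately).
#' @slot accessions A data.frame with `accession_id`, `display_code`,
#'   `category`, `composition` (comma-joined subgenome labels).
#' @slot edits Named list (by accession) of per-chromosome edit tables.
#' @slot truth Named list of ground-truth data.frames: `haplotypes`,
#'   `introgressions`, `deletions`, `missing`, `repeat_loci`.
#' @slot config The [panelSimConfig()] list used.
#' @export
setClass("WheatPanelSim",
         slots = c(genome = "DNAStringSet", targets = "TargetSet",
                   repeats = "DNAStringSet", accessions = "data.frame",
                   edits = "list", truth = "list", config = "list"))

setValidity("WheatPanelSim", function(object) {
  need <- c("accession_id", "display_code", "category", "composition")
  miss <- setdiff(need, colnames(object@accessions))
  if (length(miss)) {
    return(paste("missing accession columns:", paste(miss, collapse = ", ")))
  }
  if (sum(object@accessions$category == "reference") != 1) {
    return("panel must contain exactly one reference accession")
  }
  ploidy <- lengths(strsplit(object@accessions$composition, ","))
  if (any(ploidy %% 2 != 0)) return("ploidy must be even")
  TRUE
})

#' Accessors for WheatPanelSim
#'
#' @param x A `WheatPanelSim`.
#' @return The respective slot.
#' @export
simGenome <- function(x) x@genome

#' @rdname simGenome
#' @export
simTargets <- function(x) x@targets

#' @rdname simGenome
#' @export
simRepeats <- function(x) x@repeats

#' @rdname simGenome
#' @export
simAccessions <- function(x) x@accessions

#' @rdname simGenome
#' @export
simTruth <- function(x) x@truth

#' @rdname simGenome
#' @export
simEdits <- function(x) x@edits

#' @rdname simGenome
#' @export
simConfig <- function(x) x@config

setMethod("show", "WheatPanelSim", function(object) {
  cat("WheatPanelSim:", length(object@targets), "targets,",
      nrow(object@accessions), "accessions (",
      paste(names(table(object@accessions$category)),
            table(object@accessions$category),
            sep = "=", collapse = ", "), ")\n")
  cat("  genome:", paste(names(object@genome), collapse = ", "),
      "(", sum(lengths(object@genome)), "bp )\n")
})
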