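## High-stringency bait design: repeat soft-masking, 120-nt/60-nt candidate
## tiling, genome-wide specificity screening and filtering, plus per-target
## coverage statistics.

#' Soft-mask genomic copies of repeat library elements
#'
#' Marks every genomic interval that matches a repeat library sequence (or its
#' reverse complement) over at least `min_match_len` bases at a mismatch
#' fraction of at most `max_mismatch_fraction`. Matching is seeded exact-match
#' extension along gapless alignment diagonals: substrings of an element mask
#' independently, so the two halves of an element interrupted by a nested
#' insertion are still masked by the intact library entry. The masked
#' intervals are merged per chromosome.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param repeat_library A [Biostrings::DNAStringSet] of repeat elements.
#' @param min_match_len Minimum aligned length to mask (default 60).
#' @param max_mismatch_fraction Maximum mismatch fraction within the aligned
#'   window (default 0.1).
#' @param seed_len Exact seed length used to find candidate diagonals.
#' @return A named list (by chromosome) of [IRanges::IRanges] of masked
#'   intervals (1-based closed), sorted and non-overlapping.
#' @export
maskRepeats <- function(genome, repeat_library, min_match_len = 60,
                        max_mismatch_fraction = 0.1, seed_len = 16) {
  chromChars <- lapply(as.character(genome), .charVec)
  empty <- setNames(lapply(names(genome), function(x) IRanges()),
                    names(genome))
  if (!length(repeat_library)) {
    warning("empty repeat library: nothing masked")
    return(empty)
  }
  maxmm <- floor(max_mismatch_fraction * min_match_len)
  hits <- lapply(names(genome), function(cn) IRanges())
  names(hits) <- names(genome)
  for (el in as.character(repeat_library)) {
    if (nchar(el) < min_match_len) next
    pl <- .diagonalPlacements(el, chromChars, seed_len = seed_len)
    for (k in seq_len(nrow(pl))) {
      pm <- .placementMismatch(el, chromChars[[pl$chrom[k]]],
                               pl$start[k], pl$strand[k])
      if (is.null(pm)) next
      qs <- .qualifyingWindows(pm$mism, min_match_len, maxmm)
      if (!length(qs)) next
      ## window starts are relative to the clipped alignment; convert to
      ## genomic coordinates
      g0 <- max(1L, pl$start[k])
      ir <- reduce(IRanges(g0 + qs - 1L, width = min_match_len))
      hits[[pl$chrom[k]]] <- c(hits[[pl$chrom[k]]], ir)
    }
  }
  lapply(hits, function(x) sort(reduce(x)))
}

#' Tile 120-nt probe candidates across a target interval
#'
#' Candidates start at the target start and advance by `step` (default 60 nt,
#' i.e. 50% probe-probe overlap); the last start is the largest offset such
#' that the probe fits inside the span, giving
#' `floor((span - probe_len)/step) + 1` candidates.
#'
#' @param target_start,target_end 1-based closed target interval.
#' @param chrom Chromosome name.
#' @param gene_id Gene identifier the candidates belong to.
#' @param genome Optional [Biostrings::DNAStringSet] to extract probe
#'   sequences from.
#' @param probe_len Probe length (default 120 nt).
#' @param step Tiling step (default 60 nt).
#' @return A data.frame of candidates with unset status.
#' @export
tileCandidates <- function(target_start, target_end, chrom = "chr",
                           gene_id = "gene", genome = NULL,
                           probe_len = 120, step = 60) {
  span <- target_end - target_start + 1L
  if (span < probe_len) {
    stop("target span ", span, " is shorter than probe length ", probe_len)
  }
  offs <- seq(0L, span - probe_len, by = step)
  starts <- target_start + offs
  seqs <- rep(NA_character_, length(starts))
  if (!is.null(genome)) {
    cc <- as.character(genome[[chrom]])
    seqs <- substring(cc, starts, starts + probe_len - 1L)
  }
  data.frame(
    probe_id = sprintf("%s_p%03d", gene_id, seq_along(starts)),
    gene_id = gene_id, chrom = chrom,
    start = as.integer(starts), end = as.integer(starts + probe_len - 1L),
    sequence = seqs,
    masked_fraction = NA_real_, hyb_hits = NA_integer_,
    status = NA_character_, stringsAsFactors = FALSE)
}

#' Fraction of a probe overlapped by soft-masked sequence
#'
#' @param probes A probe data.frame (as from [tileCandidates()]).
#' @param mask_track Masked intervals per chromosome, as returned by
#'   [maskRepeats()].
#' @return The probe data.frame with `masked_fraction` filled in.
#' @export
probeMaskedFraction <- function(probes, mask_track) {
  probes$masked_fraction <- vapply(seq_len(nrow(probes)), function(i) {
    mt <- mask_track[[probes$chrom[i]]]
    if (is.null(mt) || !length(mt)) return(0)
    ir <- IRanges(probes$start[i], probes$end[i])
    ov <- intersect(ir, mt)
    sum(width(ov)) / width(ir)
  }, numeric(1))
  probes
}

#' Count strong predicted hybridization sites of probes in a genome
#'
#' For each probe, counts genomic sites (both strands) where the probe aligns
#' gaplessly over at least `min_aln_len` bases with identity at least
#' `min_identity`. Candidate sites are found by exact `seed_len`-mer matches
#' and verified with a sliding mismatch window, so the probe's own locus
#' always counts as one hit. The defaults concretize "multiple strong
#' predicted hybridization sites"; both thresholds are configurable because
#' hybridization strength has no single canonical definition. For
#' homoeologue-specific designs `min_identity` must exceed the identity
#' between homoeologous promoters, otherwise every probe reports its
#' homoeologous loci as hits.
#'
#' @param probes A probe data.frame with a `sequence` column, or a character
#'   vector of probe sequences.
#' @param genome A [Biostrings::DNAStringSet].
#' @param seed_len Exact seed length (default 16).
#' @param min_identity Minimum identity within the qualifying window
#'   (default 0.90).
#' @param min_aln_len Qualifying window length (default 80).
#' @return The probe data.frame with `hyb_hits` filled in (or an integer
#'   vector when `probes` is a character vector).
#' @export
specificityScreen <- function(probes, genome, seed_len = 16,
                              min_identity = 0.90, min_aln_len = 80) {
  seqsOnly <- is.character(probes)
  seqs <- if (seqsOnly) probes else probes$sequence
  hits <- .batchedScreen(seqs, genome, seed_len = seed_len,
                         min_identity = min_identity,
                         min_aln_len = min_aln_len)
  if (seqsOnly) return(hits)
  probes$hyb_hits <- hits
  probes
}

#' Set probe status from masking and specificity results
#'
#' A probe is `removed_masked` when 25% or more of it overlaps soft-masked
#' sequence (the masked test is applied first), `removed_multihit` when it has
#' more than one strong predicted hybridization site, and `retained`
#' otherwise. Filtering is idempotent and order-independent.
#'
#' @param probes A probe data.frame with `masked_fraction` and `hyb_hits`
#'   populated.
#' @param max_masked Masked-fraction removal threshold (default 0.25,
#'   inclusive).
#' @param max_hits Maximum allowed hybridization sites (default 1).
#' @return A [ProbeSet-class] with `status` set.
#' @export
filterProbes <- function(probes, max_masked = 0.25, max_hits = 1) {
  if (any(is.na(probes$masked_fraction)) || any(is.na(probes$hyb_hits))) {
    stop("masked_fraction and hyb_hits must be populated before filtering")
  }
  status <- ifelse(probes$masked_fraction >= max_masked, "removed_masked",
                   ifelse(probes$hyb_hits > max_hits, "removed_multihit",
                          "retained"))
  probes$status <- status
  new("ProbeSet", probes = probes)
}

#' Per-target coverage by retained probes
#'
#' @param probeset A [ProbeSet-class] (or probe data.frame with status set).
#' @param target_start,target_end 1-based closed target interval.
#' @param gene_id Target gene; only its probes are considered.
#' @return A list with `covered_bp` (union length of retained probe intervals
#'   intersected with the target) and `percent` (via [percentRounded()] to one
#'   decimal).
#' @export
targetCoverage <- function(probeset, target_start, target_end, gene_id) {
  p <- if (is(probeset, "ProbeSet")) retainedProbes(probeset) else
    probeset[!is.na(probeset$status) & probeset$status == "retained", ]
  p <- p[p$gene_id == gene_id, , drop = FALSE]
  tgt <- IRanges(target_start, target_end)
  cov <- 0L
  if (nrow(p)) {
    ir <- reduce(IRanges(p$start, p$end))
    cov <- sum(width(intersect(ir, tgt)))
  }
  list(covered_bp = as.integer(cov),
       percent = percentRounded(cov, width(tgt), 1))
}

#' Design baits for a whole target catalogue
#'
#' Runs the full high-stringency workflow: soft-mask the genome against the
#' repeat library, tile 120-nt candidates every 60 nt across every target,
#' compute masked fractions and genome-wide hybridization hit counts, and set
#' the retention status of every candidate.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param targetset A [TargetSet-class].
#' @param repeat_library A [Biostrings::DNAStringSet]; may be empty.
#' @param probe_len,step Tiling geometry (defaults 120/60 nt).
#' @param mask_min_len,mask_max_mismatch Masking thresholds passed to
#'   [maskRepeats()].
#' @param seed_len,min_identity,min_aln_len Specificity screen thresholds
#'   passed to [specificityScreen()].
#' @return A [ProbeSet-class] covering all targets.
#' @export
designBaits <- function(genome, targetset, repeat_library,
                        probe_len = 120, step = 60,
                        mask_min_len = 60, mask_max_mismatch = 0.1,
                        seed_len = 16, min_identity = 0.90,
                        min_aln_len = 80) {
  mask <- if (length(repeat_library)) {
    maskRepeats(genome, repeat_library, min_match_len = mask_min_len,
                max_mismatch_fraction = mask_max_mismatch,
                seed_len = seed_len)
  } else {
    setNames(lapply(names(genome), function(x) IRanges()), names(genome))
  }
  tg <- targetRanges(targetset)
  cand <- do.call(rbind, lapply(seq_along(tg), function(i) {
    tileCandidates(start(tg[i]), end(tg[i]),
                   chrom = as.character(seqnames(tg[i])),
                   gene_id = tg$gene_id[i], genome = genome,
                   probe_len = probe_len, step = step)
  }))
  cand <- probeMaskedFraction(cand, mask)
  ## probes already >= 25% masked are removed regardless of hits; skip the
  ## (expensive) screen for them and mark their hit count at the own locus
  toScreen <- cand$masked_fraction < 0.25
  cand$hyb_hits <- 1L
  if (any(toScreen)) {
    cand$hyb_hits[toScreen] <-
      specificityScreen(cand$sequence[toScreen], genome,
                        seed_len = seed_len, min_identity = min_identity,
                        min_aln_len = min_aln_len)
  }
  filterProbes(cand)
}
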