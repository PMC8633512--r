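---
title: "Methods: homoeologue-specific promoter capture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeologue-specific promoter capture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bread wheat is an allohexaploid (AABBDD): most genes exist as three
homoeologous copies, one per subgenome, typically 90-97% identical in their
regulatory regions. Target-capture sequencing of promoters in such a genome
only yields interpretable results if each 120-nt RNA bait enriches fragments
from *its own* homoeologue; otherwise reads from the two sister copies
contaminate every variant call. `promcap` implements the full desk-side
workflow around that requirement:

1. **Bait design** (`designBaits`): repeat soft-masking, start-anchored
   tiling of 120-nt candidates every 60 nt across each target (the ~1700 bp
   of promoter + 5'UTR upstream of the annotated ATG), a genome-wide
   specificity screen, and removal of candidates that are ≥ 25% masked or
   have more than one strong predicted hybridization site.
2. **Capture profiling** (`captureSummaries`, `subgenomeCaptureFractions`):
   per-base depth over each target window, captured lengths partitioned into
   promoter / 5'UTR / exon-intron, and per-accession subgenome presence
   compared with the pattern expected from the accession's genome
   composition (a DD diploid must show depth only on the D pseudo-
   chromosome, an AABB tetraploid only on A and B, and so on).
3. **Haplotype analysis** (`groupHaplotypes` and friends): per accession and
   target, the signature of homozygous SNPs and small InDels (≤ 20 bp,
   allele frequency 1.0, depth ≥ 10, quality ≥ 30); identical signatures
   form haplotype groups, *shared* when at least two hexaploid accessions
   carry them, otherwise *unique*; the empty signature is the
   reference-identical haplotype. Missing genes, nullisomic chromosome-arm
   clusters and cross-ploidy identical haplotypes (introgression candidates)
   fall out of the same bookkeeping.
4. **Structural variants** (`detectCliffDeletions`,
   `annotateDeletionRepeats`, `findHairpin`): deletions longer than 20 bp
   are invisible to the variant caller but appear as *cliff-edge gaps* —
   abrupt falls of coverage to zero and back. Deleted reference sequence is
   annotated against a repeat library, including decomposition of chimeric
   (nested) transposable elements, and scanned for MITE-style hairpins.
5. **TFBS deltas** (`snpWindowDelta`, `deletionTfbsContent`): each signature
   SNP is scored for gain/loss of transcription-factor binding sites by
   scanning the ±5 bp window (an 11-mer) around the wild-type and mutant
   alleles against an IUPAC consensus library at 100% match, with
   species-duplicate hits collapsed by (motif name, matched interval).

`runPipeline` chains stages 2-5 over a directory of standard files (FASTA,
GFF3, targets/accessions TSV, per-accession VCF and bedGraph) and is fully
deterministic.

# The synthetic panel

Real panel data for this design is archive-scale (hundreds of gigabases of
reads), so the package ships a first-class simulator whose planted truth
drives the whole test suite. `panelSimConfig()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_homoeo_groups` | 30 | homoeologous triads (one copy per subgenome) |
| `subgenomes` | A, B, D | one 93 kb pseudo-chromosome each |
| `homoeologue_divergence` | 0.08 | per-base substitution rate applied to the B and D copies |
| `target_span` | 1700 bp | promoter (1465 bp) + 5'UTR (235 bp) upstream of each ATG |
| panel | 1 reference + 10 commercial + 4 landraces + 2 diploid relatives + 1 AABB tetraploid | mixed-ploidy accession panel |
| `haplotype_snp_geometric_p` | 0.5 | variants per planted haplotype ~ geometric, truncated to 1..25 |
| `p_reference_only` | 0.25 | targets with no variation at all among hexaploids |
| `relative_snp_range` | 8–18 | variants per target in diploid relatives |
| TE | 512 bp chimera | 284 bp outer element with a 228 bp MITE (25 bp terminal inverted repeats, 178 bp loop) nested inside |
| `capture$fragment_len_range` | 400–600 bp | sheared fragment lengths |
| `capture$min_overlap` | 50 bp | minimum probe–fragment overlap for capture |
| `capture$max_mismatch_fraction` (tau) | 0.10 | binding tolerance; the specificity analyses run at 0.04 |
| `capture$mean_fragments_per_target` | 200 | gives hexaploid depths of roughly 15–60x and diploid depths ~3x higher |

The panel sizes are a deliberate desk-scale rendition of a real capture
panel (which would have ~90 accessions and ~900 targets): large enough that
every planted phenomenon — shared and related haplotypes, private
signatures, introgressed donor signatures, a nullisomic arm, nested TE
deletions — occurs several times, small enough that the full pipeline runs
in about two minutes.

Planted truth includes: the realized haplotype assignment of every hexaploid
accession at every target; the diploid donor's signature copied verbatim
into two hexaploid recipients at three A-subgenome targets; the 512 bp
chimera deleted from five carriers (one further accession loses only the
nested MITE, mirroring independent excision of the inner element); one
accession missing an entire gene, one missing only the promoter, and one
commercial accession nullisomic for the 1BS arm (all 15 targets on it
deleted). Variant positions are drawn on a 50 bp grid inside the target so
that planted variation alone can never locally exceed the binding tolerance;
this keeps truth recovery a property of the method rather than of luck, and
the recovery tests therefore demand *exact* equality.

## The capture binding model

Hybridization is modelled at the level of probe *placements*: each retained
probe occupies its own locus and the positionally homoeologous locus on
every other chromosome the accession carries (the toy genome uses an
identical layout per subgenome, so homoeologous coordinates coincide). A
probe binds a placement when its mismatch fraction over the whole 120-nt
placement is at most tau — hybridization integrates the full bait length,
which is also why real 120-nt RNA baits tolerate diverged templates — and a
fragment is captured when it overlaps a bound placement by at least
`min_overlap` bases. An earlier formulation that evaluated mismatches only
over the probe–fragment overlap was discarded: a 50 bp overlap can by chance
be locally clean even on a homoeologous placement with 8% divergence, so
that rule leaks cross-subgenome capture at any tau and no screen can prevent
it.

Captured fragments pile into reference-coordinate depth on their origin
chromosome; bases deleted in an accession receive no coverage, which is what
makes planted deletions recoverable with exact breakpoints. *Cross-subgenome
captured bases* are counted at the binding level: overlap bases of captured
fragments whose binding probe originates from a different subgenome than the
fragment. With the default screen this count is structurally zero at
tau = 0.04 (see below) and reappears at tau ≥ divergence, reproducing the
qualitative cross-hybridization behaviour of diverged diploid relatives.

## Screen stringency and the zero-cross-capture guarantee

`specificityScreen` counts genomic sites where a probe aligns gaplessly over
at least `min_aln_len` bases at identity ≥ `min_identity` (seeded
exact-16-mer candidate diagonals, verified by a sliding mismatch window).
Function defaults are 0.90 over 80 bp; the synthetic pipeline screens at
**0.96 over 100 bp**, and this is not a free choice: homoeologous promoters
at divergence 0.08 sit near 0.92 identity, so any screen threshold at or
below that identity would mark essentially every probe multi-hit and retain
none, while a threshold of 0.96/100 yields a clean invariant — every
retained probe has ≥ 5 mismatches in every 100-window of every homoeologous
placement, hence a full-placement mismatch fraction ≥ 5/120 ≈ 0.042 > 0.04,
hence zero cross-subgenome binding at tau = 0.04, deterministically. About
20% of candidates are removed by the screen on the synthetic genome (the
real high-stringency design lost over half), and the survivors still give
complete target coverage because 400–600 bp fragments reach across gaps of
several probe positions.

# Numerical and convention choices

* **Coordinates.** Internally everything is 1-based closed
  (GRanges/IRanges); 0-based half-open appears only in BED/bedGraph files,
  converted by `rtracklayer`. Report positions upstream of the ATG use
  negative offsets (`atgOffset`), e.g. position −143.
* **Rounding.** All printed percentages and rates use half-away-from-zero
  rounding (`percentRounded`, `roundHalfAway`): 22.03% prints as 22,
  92.506% as 93. R's default banker's rounding would disagree on exact
  halves.
* **Tiling.** Candidates are start-anchored: starts 0, 60, …,
  `floor((span-120)/60)*60`, giving `floor((span-120)/60)+1` candidates; a
  full 1700 bp target yields 27 candidates covering 1680 bp. No extra
  end-anchored probe is added; end-handling conventions differ between
  designs and the last 20 bp are reached by fragment overhang anyway.
* **Masking.** `maskRepeats` masks the union of sliding `min_match_len`
  windows whose mismatch fraction is within threshold along each seeded
  alignment diagonal. Substrings mask independently, so the two halves of
  an element interrupted by a nested insertion are still masked by the
  intact library entry — exactly the situation the planted chimera creates.
* **Homozygosity.** Allele frequency is read from a configurable INFO key
  (default `AF`); the homozygous filter uses af ≥ 1 − 10⁻⁶ to absorb float
  representation of 1.0, depth ≥ 10 and quality ≥ 30, and routes InDels
  > 20 bp out of signatures (they are depth-space events).
* **Grouping.** The comparison set for the shared/unique rule is the
  hexaploid accessions; relatives are overlaid afterwards by
  `crossPloidySharing`, and sharing requires identity of the *full*
  signature, InDels included. Incompletely captured accessions
  (< 50% of the target at depth ≥ 10) are excluded from grouping rather
  than treated as reference-identical. Haplotype labels are the subgenome
  letter plus a rank: reference-identical first, then decreasing member
  count, ties broken by first variant position then signature string — an
  arbitrary but deterministic convention.
* **Gene status.** The "promoter window" for status calls is the promoter
  partition alone (not promoter + 5'UTR): a promoter replaced by foreign
  sequence while the 5'UTR and first exon still capture must classify as
  promoter-absent-CDS-present, not as captured. Windows below 100 captured
  bp count as absent. Nullisomic-arm flags require every target on the arm
  (≥ 5 of them) missing while the sister arm keeps at least one captured
  target.
* **Cliff-edge deletions.** A deletion is a maximal run of depth ≤ 0 of
  length ≥ 21 bp whose flanks reach depth ≥ 10 within ≤ 5 bp. Runs touching
  the window boundary cannot be sized and are reported separately as
  truncated (they feed the promoter-absent logic instead). The 100 bp
  small/large split is kept as a class label only.
* **Hairpins.** `findHairpin` searches all pairs of equal-length gapless
  arms with loop between 3 and 200 bp, maximizing matches − mismatches at
  stem identity ≥ 0.8; ties break to the leftmost, then longest stem. The
  exhaustive all-pairs oracle in the test suite mirrors these exact
  conventions. Because flanking complementarity can extend a planted stem,
  recovered stems may exceed the constructed length; tests assert "at
  least" the built stem.
* **TFBS matching.** 100% IUPAC consensus matching, both strands by
  default, `N` never matches; dedup by (name, matched interval). The ±5 bp
  SNP window truncates at target boundaries rather than shifting. No
  position-weight-matrix scoring and no claim of functionality — these are
  candidate sites.
* **Global identity.** `pairwiseTargetIdentity` uses Needleman–Wunsch with
  unit scores and gap −2; percent identity is identities over aligned
  columns, gaps included (the convention used when comparing target
  sequences between assembly versions).

# What the simulator does not emulate

No read-level errors, no PCR duplicates, no mapping ambiguity (fragments
pile onto their true origin), no heterozygosity (the pipeline's homozygous
filter is exercised with constructed records instead), no hybridization
thermodynamics beyond the single mismatch-fraction tolerance, and no
insertions relative to the reference in sequence space (they are emitted as
VCF records but, as in depth space generally, invisible to coverage).
Passing the recovery suite therefore demonstrates that the *analysis logic*
is correct under clean signals of realistic geometry; it does not
demonstrate robustness to alignment artefacts or library-preparation noise
in real data.

# Problem sizes

The test suite runs the full default panel once (30 triads × 3 subgenomes,
18 accessions, ~2400 probe candidates, ~6.7 Mb of simulated fragments per
hexaploid) plus a half-size panel for module tests; brute-force oracle
comparisons use 500 random sequences for the motif scanner, 200 random
profiles for the cliff detector and sequences up to 300 bp for the hairpin
finder. These sizes were chosen so each planted phenomenon recurs several
times while the whole suite stays interactive.

# Known limitations

* The specificity guarantee is proven for the simulator's positionally
  aligned homoeologues; real homoeologues contain indels, so real screens
  should use a gapped aligner for the hit count (the module's interface
  does not change).
* Haplotype identity is exact string identity of variant records; two
  pipelines normalizing indels differently would fragment groups.
* The repeat annotator is gapless per diagonal; highly decayed TE copies
  are better served by a dedicated repeat aligner.
* With no real archived data in scope, printed-value checks exercise the
  reporting arithmetic on published counts rather than re-deriving those
  counts from raw reads.
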